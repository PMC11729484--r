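# Estimation of the effective exo lumbar extension moment from elastic-band
# mechanics: band stretch -> band force (manufacturer force-displacement
# curve) -> peak extension moment (force x moment arm about L5/S1), corrected
# multiplicatively for band hysteresis and moment/loading timing mismatch,
# then reduced by the lumbar flexion moment of the trunk-worn device mass.

#' Elastic-band force-displacement curve
#'
#' Holds ordered (displacement, force) samples for the loading branch and,
#' optionally, the unloading branch of the hysteresis loop.
#'
#' @param displacement Strictly increasing displacements, m.
#' @param force Non-negative, non-decreasing forces on the loading branch, N.
#' @param unloading_force Optional unloading-branch forces at the same
#'   displacements; must not exceed the loading force anywhere.
#'
#' @return An object of class `band_curve`.
#' @examples
#' band_curve(c(0, 0.1, 0.2), c(0, 100, 250))
#' @export
band_curve <- function(displacement, force, unloading_force = NULL) {
  if (length(displacement) < 2 || length(displacement) != length(force)) {
    abort_domain("Need at least two (displacement, force) samples of equal length.")
  }
  if (any(diff(displacement) <= 0)) {
    abort_domain("Displacements must be strictly increasing.")
  }
  check_nonneg(force, "force")
  check_nonneg(displacement, "displacement")
  if (any(diff(force) < 0)) {
    abort_domain("Loading-branch forces must be non-decreasing.")
  }
  if (!is.null(unloading_force)) {
    if (length(unloading_force) != length(force)) {
      abort_domain("`unloading_force` must match the loading samples in length.")
    }
    check_nonneg(unloading_force, "unloading_force")
    if (any(unloading_force > force + 1e-9)) {
      abort_domain("Unloading force must not exceed loading force at equal displacement.")
    }
  }
  structure(
    list(displacement = displacement, force = force,
         unloading_force = unloading_force),
    class = "band_curve"
  )
}

#' @export
print.band_curve <- function(x, ...) {
  cat(sprintf("<band_curve> %d samples, 0-%.3f m, 0-%.1f N%s\n",
              length(x$displacement), max(x$displacement), max(x$force),
              if (is.null(x$unloading_force)) "" else ", with unloading branch"))
  invisible(x)
}

#' Band force at a given stretch
#'
#' Piecewise-linear interpolation on the loading branch. Stretch beyond the
#' sampled range is an error: elastic bands stiffen nonlinearly, so silent
#' extrapolation would fabricate assistance.
#'
#' @param stretch Band stretch, m (vectorised).
#' @param curve A [band_curve()].
#' @return Force in N.
#' @examples
#' bc <- band_curve(c(0, 0.1, 0.2), c(0, 100, 250))
#' band_force(0.15, bc) # 175 N
#' @export
band_force <- function(stretch, curve) {
  stopifnot(inherits(curve, "band_curve"))
  check_nonneg(stretch, "stretch")
  rng <- range(curve$displacement)
  if (any(stretch < rng[1] - 1e-12) || any(stretch > rng[2] + 1e-12)) {
    abort_domain(sprintf(
      "Stretch outside the sampled range [%.4f, %.4f] m; no extrapolation.",
      rng[1], rng[2]))
  }
  stats::approx(curve$displacement, curve$force, xout = stretch,
                method = "linear", rule = 1)$y
}

#' Exo moment arm about L5/S1
#'
#' Sum of the anatomical depth from the L5/S1 joint centre to the skin of the
#' low back and the measured offset from the skin to the elastic bands.
#'
#' @param l5s1_to_skin Joint-centre-to-skin distance, m.
#' @param skin_to_band Skin-to-band distance, m.
#' @return Moment arm in m.
#' @export
moment_arm <- function(l5s1_to_skin, skin_to_band) {
  check_nonneg(l5s1_to_skin, "l5s1_to_skin")
  check_nonneg(skin_to_band, "skin_to_band")
  l5s1_to_skin + skin_to_band
}

#' Peak lumbar extension moment generated by the bands
#'
#' @param force Peak band force, N.
#' @param arm Moment arm about L5/S1, m.
#' @return Moment in Nm.
#' @export
peak_extension_moment <- function(force, arm) {
  check_nonneg(force, "force")
  check_nonneg(arm, "arm")
  force * arm
}

#' Lumbar flexion moment from the trunk-worn device mass
#'
#' @param device_mass Trunk-worn exo mass, kg.
#' @param com_distance Horizontal distance of that mass from L5/S1, m.
#' @param gravity m/s^2.
#' @return Moment in Nm.
#' @export
weight_flexion_moment <- function(device_mass, com_distance, gravity = 9.81) {
  check_nonneg(device_mass, "device_mass")
  check_nonneg(com_distance, "com_distance")
  check_pos(gravity, "gravity")
  device_mass * gravity * com_distance
}

#' Exosuit specification
#'
#' Everything needed to estimate the effective exo lumbar extension moment:
#' the band force-displacement curve, the measured maximum band stretch,
#' moment-arm components, trunk-worn device mass and its moment arm, and the
#' multiplicative hysteresis and timing correction factors.
#'
#' `hysteresis_factor` scales the delivered force down for elastic energy
#' loss; `timing_factor` accounts for peak exo moment not coinciding exactly
#' with peak lumbar loading. Both default to 1 (no correction); replicating a
#' specific device requires the factors measured for it.
#'
#' @param band_curve A [band_curve()].
#' @param max_stretch Maximum band stretch at the deepest part of the lift, m.
#' @param l5s1_to_skin,skin_to_band Moment-arm components, m.
#' @param device_mass Trunk-worn exo mass, kg.
#' @param device_com_distance Horizontal distance of the trunk-worn mass from
#'   L5/S1, m.
#' @param hysteresis_factor,timing_factor Multiplicative corrections in (0, 1].
#'
#' @return An object of class `exo_spec`.
#' @export
exo_spec <- function(band_curve, max_stretch, l5s1_to_skin, skin_to_band,
                     device_mass = 0, device_com_distance = 0,
                     hysteresis_factor = 1, timing_factor = 1) {
  stopifnot(inherits(band_curve, "band_curve"))
  check_nonneg(max_stretch, "max_stretch")
  check_nonneg(l5s1_to_skin, "l5s1_to_skin")
  check_nonneg(skin_to_band, "skin_to_band")
  check_nonneg(device_mass, "device_mass")
  check_nonneg(device_com_distance, "device_com_distance")
  for (f in c("hysteresis_factor", "timing_factor")) {
    v <- get(f)
    if (!is.finite(v) || v <= 0 || v > 1) {
      abort_domain(sprintf("`%s` must lie in (0, 1].", f))
    }
  }
  structure(
    list(band_curve = band_curve, max_stretch = max_stretch,
         l5s1_to_skin = l5s1_to_skin, skin_to_band = skin_to_band,
         device_mass = device_mass, device_com_distance = device_com_distance,
         hysteresis_factor = hysteresis_factor, timing_factor = timing_factor),
    class = "exo_spec"
  )
}

#' @export
print.exo_spec <- function(x, ...) {
  cat(sprintf(
    "<exo_spec> stretch %.3f m, arm %.3f m, mass %.2f kg, h=%.2f t=%.2f\n",
    x$max_stretch, moment_arm(x$l5s1_to_skin, x$skin_to_band),
    x$device_mass, x$hysteresis_factor, x$timing_factor))
  invisible(x)
}

#' Effective exo lumbar extension moment
#'
#' Runs the full estimation chain: band force at maximum stretch, peak
#' extension moment (force x moment arm), multiplicative hysteresis and
#' timing corrections, then subtraction of the device-weight flexion moment.
#' The result is the exo moment fed to the damage model — the reduction in
#' peak lumbar moment the exo provides. A negative result (device weight
#' outweighing assistance) is floored at 0 with a warning.
#'
#' @param spec An [exo_spec()].
#' @param gravity m/s^2.
#' @return A one-row tibble of class `exo_moment_estimate` with every
#'   component of the estimate: `peak_band_force`, `moment_arm`,
#'   `peak_extension_moment`, `weight_flexion_moment`, `effective_exo_moment`.
#' @examples
#' bc <- band_curve(c(0, 0.30), c(0, 900))
#' spec <- exo_spec(bc, max_stretch = 0.10, l5s1_to_skin = 0.08,
#'                  skin_to_band = 0.02, device_mass = 2,
#'                  device_com_distance = 0.1,
#'                  hysteresis_factor = 0.9, timing_factor = 0.95)
#' effective_exo_moment(spec)
#' @export
effective_exo_moment <- function(spec, gravity = 9.81) {
  stopifnot(inherits(spec, "exo_spec"))
  f <- band_force(spec$max_stretch, spec$band_curve)
  arm <- moment_arm(spec$l5s1_to_skin, spec$skin_to_band)
  peak <- peak_extension_moment(f, arm)
  flex <- weight_flexion_moment(spec$device_mass, spec$device_com_distance,
                                gravity)
  eff <- peak * spec$hysteresis_factor * spec$timing_factor - flex
  if (eff < 0) {
    warn_clamp("Device-weight flexion moment exceeds corrected assistance; effective exo moment floored at 0.")
    eff <- 0
  }
  tibble::new_tibble(
    tibble::tibble(
      peak_band_force = f,
      moment_arm = arm,
      peak_extension_moment = peak,
      weight_flexion_moment = flex,
      effective_exo_moment = eff
    ),
    class = "exo_moment_estimate"
  )
}
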
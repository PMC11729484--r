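# Parameter sweeps and breakeven analysis: how exo assistance, lifting
# repetitions, and object weight interact to change cumulative back damage,
# and where the exo's damage reduction is exactly cancelled by doing more.

# TRUE when the moment -> load map is affine (always, for this params class);
# kept as a hook should a nonlinear map ever be added.
.has_affine_map <- function(params) {
  is.finite(params$moment_to_load_offset) && is.finite(params$moment_to_load_gain)
}

#' Damage-change surface over exo moment and performance increase
#'
#' For each grid cell (exo moment, performance increase) computes the percent
#' change in cumulative damage relative to the nominal no-exo task. In
#' `"repetitions"` mode the increase scales the number of lifts; in
#' `"weight"` mode it scales the object mass. Repetition-mode surfaces are
#' independent of the nominal mass (repetitions enter linearly, so the
#' nominal damage cancels); weight-mode surfaces are not, which is why modest
#' weight increases can cancel an exo's benefit on already-heavy objects.
#'
#' @param mode `"repetitions"` or `"weight"`.
#' @param nominal_mass Nominal object mass, kg.
#' @param distance Horizontal object-to-hip distance, m.
#' @param exo_moments Exo-moment axis, Nm.
#' @param increases Performance-increase axis, percent.
#' @param nominal_reps Nominal lift count; percent-change output is invariant
#'   to this choice.
#' @param params A [damage_params()] object.
#' @return A tibble in long format: `exo_moment_nm`, `increase_pct`,
#'   `damage_change_pct`, plus `mode`, `nominal_mass_kg`, `distance_m`.
#' @examples
#' g <- damage_change_grid("repetitions", nominal_mass = 22.7, distance = 0.7,
#'                         exo_moments = c(0, 30), increases = c(0, 20))
#' subset(g, exo_moment_nm == 30 & increase_pct == 20) # ~ -62%
#' @export
damage_change_grid <- function(mode = c("repetitions", "weight"),
                               nominal_mass = 45, distance = 0.6,
                               exo_moments = 0:50, increases = 0:100,
                               nominal_reps = 1000,
                               params = damage_params()) {
  mode <- match.arg(mode)
  if (length(exo_moments) == 0 || length(increases) == 0) {
    abort_domain("Sweep axes must be non-empty.")
  }
  check_nonneg(exo_moments, "exo_moments")
  check_nonneg(increases, "increases")
  check_pos(nominal_mass, "nominal_mass")
  check_pos(distance, "distance")

  nominal <- lift_task(nominal_mass, distance, nominal_reps)
  d0 <- cumulative_damage(nominal, 0, params)$cumulative_damage

  grid <- tidyr::expand_grid(exo_moment_nm = exo_moments,
                             increase_pct = increases)
  scale <- 1 + grid$increase_pct / 100
  mass <- if (mode == "weight") nominal_mass * scale else nominal_mass
  reps <- if (mode == "repetitions") nominal_reps * scale else nominal_reps
  lm <- load_moment(mass, distance, params$gravity)
  em <- suppressWarnings(effective_moment(lm, grid$exo_moment_nm))
  d <- reps * suppressWarnings(per_lift_damage(em, params))
  grid$damage_change_pct <- percent_change_damage(d, d0)
  grid$mode <- mode
  grid$nominal_mass_kg <- nominal_mass
  grid$distance_m <- distance
  grid
}

#' Breakeven repetition increase for a given exo moment
#'
#' The percent increase in lifting repetitions at which the exo's cumulative
#' damage reduction is exactly cancelled. Under the log-linear S-N model with
#' an affine moment-to-load map this has the closed form
#' `100 * (10^(sn_slope * gain * exo_moment) - 1)`, independent of the
#' nominal task. `method = "bisection"` solves the same breakeven condition
#' numerically (tolerance 1e-9) at a specified nominal task; it is the route
#' for non-affine load maps and the cross-check for the closed form.
#'
#' @param exo_moment Exo moment, Nm (vectorised for the closed form).
#' @param params A [damage_params()] object.
#' @param method `"closed"` (default) or `"bisection"`.
#' @param nominal_moment Nominal load moment, Nm; required by the bisection
#'   route, which must have `exo_moment < nominal_moment`.
#' @return Breakeven repetition increase, percent.
#' @examples
#' breakeven_rep_increase(15.3) # ~79%
#' breakeven_rep_increase(42.3) # ~399%
#' @export
breakeven_rep_increase <- function(exo_moment, params = damage_params(),
                                   method = c("closed", "bisection"),
                                   nominal_moment = NULL) {
  method <- match.arg(method)
  check_nonneg(exo_moment, "exo_moment")
  if (method == "closed") {
    return(100 * (10^(params$sn_slope * params$moment_to_load_gain * exo_moment) - 1))
  }
  if (is.null(nominal_moment)) {
    abort_domain("Bisection needs a `nominal_moment`.")
  }
  check_pos(nominal_moment, "nominal_moment")
  vapply(exo_moment, function(e) {
    if (e >= nominal_moment) {
      abort_domain("Exo moment must be below the nominal load moment.")
    }
    if (e == 0) return(0)
    d0 <- per_lift_damage(nominal_moment, params)
    de <- per_lift_damage(nominal_moment - e, params)
    f <- function(x) (1 + x / 100) * de - d0
    upper <- 100
    while (f(upper) < 0) upper <- upper * 2
    stats::uniroot(f, c(0, upper), tol = 1e-9)$root
  }, numeric(1))
}

#' Breakeven weight increase for a given exo moment
#'
#' The percent increase in object weight at which the exo's damage reduction
#' is exactly cancelled, for a nominal task. While per-lift damage is
#' strictly increasing in the moment, the breakeven condition
#' `damage((1 + x) M - exo) = damage(M)` reduces to the model-independent
#' closed form `x = 100 * exo_moment / M`. A root-finder route is provided as
#' the numerical cross-check.
#'
#' @param exo_moment Exo moment, Nm.
#' @param nominal_mass Nominal object mass, kg (> 0).
#' @param distance Object-to-hip distance, m (> 0).
#' @param params A [damage_params()] object.
#' @param method `"closed"` (default) or `"bisection"`.
#' @return Breakeven weight increase, percent.
#' @examples
#' breakeven_weight_increase(15.3, nominal_mass = 45, distance = 0.6) # ~6%
#' @export
breakeven_weight_increase <- function(exo_moment, nominal_mass, distance,
                                      params = damage_params(),
                                      method = c("closed", "bisection")) {
  method <- match.arg(method)
  check_nonneg(exo_moment, "exo_moment")
  check_pos(nominal_mass, "nominal_mass")
  check_pos(distance, "distance")
  M <- load_moment(nominal_mass, distance, params$gravity)
  if (method == "closed") {
    return(100 * exo_moment / M)
  }
  vapply(exo_moment, function(e) {
    if (e == 0) return(0)
    d0 <- per_lift_damage(M, params)
    # bracket expansion may probe beyond the N_f >= 1 cap; silence it there
    f <- function(x) {
      suppressWarnings(
        per_lift_damage(max((1 + x / 100) * M - e, 0), params)) - d0
    }
    upper <- 100
    while (f(upper) < 0) upper <- upper * 2
    stats::uniroot(f, c(0, upper), tol = 1e-9)$root
  }, numeric(1))
}

#' Exo moment required to hold cumulative damage constant
#'
#' Inverse of the breakeven curves: the exo moment needed so that a given
#' percent increase in performance produces zero change in cumulative damage.
#' Weight mode: `0.01 * increase * nominal load moment` (grows linearly with
#' nominal mass). Repetition mode: `log10(1 + increase/100) / (sn_slope *
#' gain)`, independent of the nominal task.
#'
#' @param increase Performance increase, percent (vectorised).
#' @param mode `"repetitions"` or `"weight"`.
#' @param nominal_mass,distance Nominal task (needed in weight mode).
#' @param params A [damage_params()] object.
#' @return Required exo moment, Nm.
#' @examples
#' required_exo_moment(20, "weight", nominal_mass = 45, distance = 0.6) # ~53 Nm
#' required_exo_moment(20, "repetitions")                               # ~5 Nm
#' @export
required_exo_moment <- function(increase, mode = c("repetitions", "weight"),
                                nominal_mass = 45, distance = 0.6,
                                params = damage_params()) {
  mode <- match.arg(mode)
  check_nonneg(increase, "increase")
  if (mode == "weight") {
    check_pos(nominal_mass, "nominal_mass")
    check_pos(distance, "distance")
    M <- load_moment(nominal_mass, distance, params$gravity)
    0.01 * increase * M
  } else {
    log10(1 + increase / 100) / (params$sn_slope * params$moment_to_load_gain)
  }
}

#' Breakeven contour
#'
#' Tabulates [required_exo_moment()] over an increase axis: the zero-change
#' contour of the damage surface.
#'
#' @param mode `"repetitions"` or `"weight"`.
#' @param nominal_mass,distance Nominal task.
#' @param increases Increase axis, percent.
#' @param params A [damage_params()] object.
#' @return A tibble: `increase_pct`, `required_exo_moment_nm`, `mode`,
#'   `nominal_mass_kg`, `distance_m`.
#' @export
breakeven_curve <- function(mode = c("repetitions", "weight"),
                            nominal_mass = 45, distance = 0.6,
                            increases = 0:100,
                            params = damage_params()) {
  mode <- match.arg(mode)
  tibble::tibble(
    increase_pct = increases,
    required_exo_moment_nm = required_exo_moment(increases, mode,
                                                 nominal_mass, distance,
                                                 params),
    mode = mode,
    nominal_mass_kg = nominal_mass,
    distance_m = distance
  )
}

#' Productivity-vs-risk demonstration scenarios
#'
#' Four modelled lifting scenarios that contrast the two routes to 20% more
#' productivity under exo assistance: (A) a nominal task — by default 22.7 kg
#' (50 lb) lifted 1000 times at a 70 cm object-to-spine distance, no exo;
#' (B) the same task with a 30 Nm exo moment; (C) the exo plus 20% more
#' repetitions; (D) the exo plus 20% more object weight. Percent damage
#' change is reported against scenario A. Increasing repetitions preserves
#' most of the exo's damage reduction; increasing weight forfeits it.
#'
#' @param nominal_mass Nominal object mass, kg.
#' @param distance Object-to-hip distance, m.
#' @param nominal_reps Nominal lift count.
#' @param exo_moment Exo moment in scenarios B-D, Nm.
#' @param increase Productivity increase applied in C and D, percent.
#' @param params A [damage_params()] object.
#' @return A tibble with one row per scenario: `scenario`, `description`,
#'   `mass_kg`, `repetitions`, `exo_moment_nm`, `cumulative_damage`,
#'   `damage_change_pct`.
#' @examples
#' productivity_scenarios()
#' @export
productivity_scenarios <- function(nominal_mass = 22.7, distance = 0.70,
                                   nominal_reps = 1000, exo_moment = 30,
                                   increase = 20,
                                   params = damage_params()) {
  s <- 1 + increase / 100
  spec <- tibble::tibble(
    scenario = c("A", "B", "C", "D"),
    description = c(
      "nominal task, no exo",
      "same task with exo",
      sprintf("exo + %d%% repetitions", round(increase)),
      sprintf("exo + %d%% object weight", round(increase))
    ),
    mass_kg = c(nominal_mass, nominal_mass, nominal_mass, nominal_mass * s),
    repetitions = c(nominal_reps, nominal_reps,
                    nominal_reps * s, nominal_reps),
    exo_moment_nm = c(0, exo_moment, exo_moment, exo_moment)
  )
  lm <- load_moment(spec$mass_kg, distance, params$gravity)
  em <- effective_moment(lm, spec$exo_moment_nm)
  spec$cumulative_damage <- spec$repetitions * per_lift_damage(em, params)
  spec$damage_change_pct <- percent_change_damage(spec$cumulative_damage,
                                                  spec$cumulative_damage[1])
  spec
}
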
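# Shared fixtures built in code.

# one ABA participant's sets table
aba_sets <- function(reps = c(14, 18, 13), exo = 35,
                     mass = 55, dist = 0.6, participant = "S01") {
  tibble::tibble(
    participant = participant,
    condition = c("A1", "B", "A2"),
    reps = as.integer(reps),
    mass_kg = mass,
    distance_m = dist,
    exo_moment_nm = c(0, exo, 0)
  )
}

# brute-force reversal oracle: enumerates the donned/doffed inequalities
# directly from the three counts
reversal_oracle <- function(a1, b, a2) (b > a1) && (a2 < b)

# brute-force interpolation oracle for band curves: scan every segment of
# the polyline and apply the two-point line formula by hand
interp_oracle <- function(curve, stretch) {
  x <- curve$displacement
  y <- curve$force
  for (i in seq_len(length(x) - 1)) {
    if (stretch >= x[i] && stretch <= x[i + 1]) {
      return(y[i] + (y[i + 1] - y[i]) * (stretch - x[i]) / (x[i + 1] - x[i]))
    }
  }
  stop("stretch outside curve range")
}
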
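test_that("load moment is weight times horizontal distance", {
  expect_equal(load_moment(0, 0.6), 0)
  expect_equal(load_moment(22.7, 0.70), 22.7 * 9.81 * 0.70)
  expect_equal(load_moment(45, 0.60), 45 * 9.81 * 0.60)
  expect_error(load_moment(-1, 0.5), class = "exofatigue_domain_error")
  expect_error(load_moment(10, -0.5), class = "exofatigue_domain_error")
})

test_that("effective moment subtracts exo assistance and clamps at zero", {
  expect_equal(effective_moment(155.9, 30), 125.9)
  expect_equal(effective_moment(100, 0), 100)
  expect_warning(em <- effective_moment(10, 50),
                 class = "exofatigue_clamp_warning")
  expect_equal(em, 0)
  expect_error(effective_moment(-1, 0), class = "exofatigue_domain_error")
})

test_that("per-lift damage follows the log-linear S-N ratio identity", {
  p <- damage_params()
  # exponential scaling: damage(M - m) / damage(M) = 10^(-slope * m),
  # to machine precision across a grid of moments inside the S-N range
  # (above ~361 Nm the N_f >= 1 cap intentionally flattens the curve)
  for (M in seq(50, 350, by = 25)) {
    for (m in c(5, 15.3, 30, 42.3)) {
      expect_equal(per_lift_damage(M - m, p) / per_lift_damage(M, p),
                   10^(-p$sn_slope * m))
    }
  }
  # strictly increasing, in (0, 1]
  grid <- seq(0, 350, by = 10)
  d <- per_lift_damage(grid, p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d > 0 & d <= 1))
})

test_that("per-lift damage ratio for a 30 Nm reduction is ~0.32", {
  p <- damage_params()
  expect_equal(per_lift_damage(155.9 - 30, p) / per_lift_damage(155.9, p),
               0.32, tolerance = 0.01)
})

test_that("affine moment-to-load offset cancels in damage ratios", {
  p0 <- damage_params()
  p1 <- damage_params(moment_to_load_offset = 500,
                      sn_intercept = damage_params()$sn_intercept +
                        damage_params()$sn_slope * 500)
  expect_equal(per_lift_damage(120, p1) / per_lift_damage(150, p1),
               per_lift_damage(120, p0) / per_lift_damage(150, p0))
})

test_that("nonphysical N_f < 1 caps damage at one with a warning", {
  p <- damage_params(sn_intercept = 1, sn_slope = 0.05)
  expect_warning(d <- per_lift_damage(100, p),
                 class = "exofatigue_cap_warning")
  expect_equal(d, 1)
})

test_that("cumulative damage is exactly linear in repetitions", {
  p <- damage_params()
  base <- cumulative_damage(lift_task(45, 0.6, 100), 20, p)
  expect_equal(cumulative_damage(lift_task(45, 0.6, 0), 20, p)$cumulative_damage, 0)
  for (k in c(2, 5, 13)) {
    scaled <- cumulative_damage(lift_task(45, 0.6, 100 * k), 20, p)
    expect_equal(scaled$cumulative_damage, k * base$cumulative_damage,
                 tolerance = 1e-15)
  }
})

test_that("cumulative damage equals the brute-force lift-by-lift sum", {
  p <- damage_params()
  task <- lift_task(22.7, 0.70, 137)
  res <- cumulative_damage(task, 30, p)
  per <- per_lift_damage(effective_moment(load_moment(22.7, 0.70), 30), p)
  expect_equal(res$cumulative_damage, sum(rep(per, 137)))
})

test_that("cumulative damage is monotone in mass, distance, reps, exo moment", {
  p <- damage_params()
  d <- function(mass, dist, reps, exo) {
    cumulative_damage(lift_task(mass, dist, reps), exo, p)$cumulative_damage
  }
  expect_lt(d(40, 0.6, 100, 20), d(45, 0.6, 100, 20))
  expect_lt(d(45, 0.5, 100, 20), d(45, 0.6, 100, 20))
  expect_lt(d(45, 0.6, 90, 20), d(45, 0.6, 100, 20))
  expect_gt(d(45, 0.6, 100, 10), d(45, 0.6, 100, 20))
})

test_that("default S-N slope is recovered from the two breakeven anchors", {
  # least-squares fit through the origin to (15.3 Nm, log10 1.79) and
  # (42.3 Nm, log10 4.99): the two printed breakeven conditions
  x <- c(15.3, 42.3)
  y <- log10(1 + c(79, 399) / 100)
  fitted_slope <- sum(x * y) / sum(x^2)
  expect_equal(damage_params()$sn_slope, fitted_slope, tolerance = 0.02)
})

test_that("percent change uses the (new - old)/old convention", {
  expect_equal(percent_change_damage(0.5, 1.0), -50)
  expect_equal(percent_change_damage(1.0, 1.0), 0)
  expect_error(percent_change_damage(1, 0),
               class = "exofatigue_comparison_error")
})

test_that("power-law damage ratio is load_ratio^C", {
  expect_equal(power_law_damage_ratio(1.0, 4), 1.0)
  expect_equal(power_law_damage_ratio(1.0, 7), 1.0)
  expect_equal(power_law_damage_ratio(0.9, 4), 0.9^4)
  expect_equal(power_law_damage_ratio(0.9, 9), 0.9^9)
  expect_error(power_law_damage_ratio(0, 4), class = "exofatigue_domain_error")
  expect_warning(power_law_damage_ratio(0.9, 12),
                 class = "exofatigue_range_warning")
})

test_that("task and parameter validation rejects bad inputs", {
  expect_error(lift_task(45, 0.6, 10.5), class = "exofatigue_domain_error")
  expect_error(lift_task(45, 0.6, -1), class = "exofatigue_domain_error")
  expect_error(lift_task(45, 0.6, 10, period = 0),
               class = "exofatigue_domain_error")
  expect_error(damage_params(sn_slope = -0.01),
               class = "exofatigue_domain_error")
  expect_error(damage_params(gravity = 0), class = "exofatigue_domain_error")
  expect_equal(lb_to_kg(50), 22.6796185)
})
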
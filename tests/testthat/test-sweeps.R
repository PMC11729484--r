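test_that("damage-change grid is monotone along both axes", {
  for (mode in c("repetitions", "weight")) {
    g <- damage_change_grid(mode, nominal_mass = 23, distance = 0.6,
                            exo_moments = seq(0, 50, by = 5),
                            increases = seq(0, 100, by = 10))
    wide <- tidyr::pivot_wider(g[c("exo_moment_nm", "increase_pct",
                                   "damage_change_pct")],
                               names_from = "increase_pct",
                               values_from = "damage_change_pct")
    m <- as.matrix(wide[-1])
    # non-increasing down the exo-moment axis, cell by cell
    expect_true(all(apply(m, 2, function(col) all(diff(col) <= 1e-9))))
    # non-decreasing along the increase axis
    expect_true(all(apply(m, 1, function(row) all(diff(row) >= -1e-9))))
  }
})

test_that("grid reference cell is zero and matches the scenario table", {
  g <- damage_change_grid("repetitions", nominal_mass = 22.7, distance = 0.70,
                          exo_moments = c(0, 30), increases = c(0, 20))
  expect_equal(g$damage_change_pct[g$exo_moment_nm == 0 & g$increase_pct == 0], 0)
  expect_equal(round(g$damage_change_pct[g$exo_moment_nm == 30 &
                                           g$increase_pct == 20]), -62)
})

test_that("repetition-mode grids are identical for any nominal mass", {
  g5 <- damage_change_grid("repetitions", nominal_mass = 5, distance = 0.6,
                           exo_moments = 0:10 * 2, increases = 0:10 * 10)
  g23 <- damage_change_grid("repetitions", nominal_mass = 23, distance = 0.6,
                            exo_moments = 0:10 * 2, increases = 0:10 * 10)
  g45 <- damage_change_grid("repetitions", nominal_mass = 45, distance = 0.6,
                            exo_moments = 0:10 * 2, increases = 0:10 * 10)
  expect_equal(g5$damage_change_pct, g23$damage_change_pct)
  expect_equal(g23$damage_change_pct, g45$damage_change_pct)
})

test_that("percent-change output is invariant to the nominal repetition count", {
  a <- damage_change_grid("repetitions", exo_moments = c(0, 20),
                          increases = c(0, 50), nominal_reps = 1000)
  b <- damage_change_grid("repetitions", exo_moments = c(0, 20),
                          increases = c(0, 50), nominal_reps = 37)
  expect_equal(a$damage_change_pct, b$damage_change_pct)
})

test_that("breakeven repetition increases reproduce the printed anchors", {
  expect_equal(breakeven_rep_increase(0), 0)
  expect_equal(round(breakeven_rep_increase(15.3)), 79)
  expect_equal(round(breakeven_rep_increase(42.3)), 399)
})

test_that("closed-form breakevens agree with the root-finder", {
  set.seed(9)
  p <- damage_params()
  for (i in 1:20) {
    # tasks kept inside the S-N validity range (per-lift damage < 1)
    exo <- runif(1, 1, 45)
    mass <- runif(1, 10, 40)
    dist <- runif(1, 0.4, 0.8)
    M <- load_moment(mass, dist)
    if (exo >= M) next
    closed_r <- breakeven_rep_increase(exo, p)
    num_r <- breakeven_rep_increase(exo, p, method = "bisection",
                                    nominal_moment = M)
    expect_equal(num_r, closed_r, tolerance = 1e-6)
    closed_w <- breakeven_weight_increase(exo, mass, dist, p)
    num_w <- breakeven_weight_increase(exo, mass, dist, p,
                                       method = "bisection")
    expect_equal(num_w, closed_w, tolerance = 1e-6)
  }
})

test_that("breakeven weight increase satisfies x * M = exo moment", {
  expect_equal(breakeven_weight_increase(0, 45, 0.6), 0)
  expect_equal(round(breakeven_weight_increase(15.3, 45, 0.6)), 6)
  set.seed(10)
  for (i in 1:10) {
    exo <- runif(1, 1, 40)
    mass <- runif(1, 10, 60)
    x <- breakeven_weight_increase(exo, mass, 0.6)
    expect_equal(x / 100 * load_moment(mass, 0.6), exo)
  }
})

test_that("required exo moment inverts the breakeven curves", {
  expect_equal(round(required_exo_moment(20, "weight", 45, 0.6)), 53)
  expect_equal(round(required_exo_moment(20, "weight", 23, 0.6)), 27)
  expect_equal(round(required_exo_moment(20, "weight", 5, 0.6)), 6)
  expect_equal(round(required_exo_moment(20, "repetitions")), 5)
  # repetitions-mode requirement is mass-independent
  expect_equal(required_exo_moment(20, "repetitions", nominal_mass = 5),
               required_exo_moment(20, "repetitions", nominal_mass = 45))
  # weight-mode requirement scales linearly with nominal mass
  expect_equal(required_exo_moment(20, "weight", 45, 0.6),
               9 * required_exo_moment(20, "weight", 5, 0.6))
  # round trip with the forward breakevens
  m <- required_exo_moment(35, "repetitions")
  expect_equal(breakeven_rep_increase(m), 35)
})

test_that("breakeven curve is strictly increasing in the increase axis", {
  for (mode in c("repetitions", "weight")) {
    bc <- breakeven_curve(mode, increases = seq(0, 100, by = 5))
    expect_true(all(diff(bc$required_exo_moment_nm) > 0))
  }
})

test_that("model trends are unchanged across object-to-hip distances", {
  ref <- damage_change_grid("weight", nominal_mass = 23, distance = 0.6,
                            exo_moments = seq(0, 50, 10),
                            increases = seq(0, 100, 20))
  for (dist in c(0.3, 0.45, 0.75, 0.9)) {
    g <- damage_change_grid("weight", nominal_mass = 23, distance = dist,
                            exo_moments = seq(0, 50, 10),
                            increases = seq(0, 100, 20))
    # repetition breakevens are distance-free; weight-mode sign structure
    # moves with the nominal moment but stays monotone
    wide <- tidyr::pivot_wider(g[c("exo_moment_nm", "increase_pct",
                                   "damage_change_pct")],
                               names_from = "increase_pct",
                               values_from = "damage_change_pct")
    m <- as.matrix(wide[-1])
    expect_true(all(apply(m, 2, function(col) all(diff(col) <= 1e-9))))
    expect_true(all(apply(m, 1, function(row) all(diff(row) >= -1e-9))))
  }
  reps_a <- breakeven_rep_increase(seq(0, 50, 10))
  expect_equal(reps_a, breakeven_rep_increase(seq(0, 50, 10)))
})

test_that("productivity scenarios contrast repetition and weight increases", {
  sc <- productivity_scenarios()
  expect_equal(sc$damage_change_pct[sc$scenario == "A"], 0)
  expect_equal(round(sc$damage_change_pct[sc$scenario == "B"]), -68)
  expect_equal(round(sc$damage_change_pct[sc$scenario == "C"]), -62)
  # weight route forfeits the reduction; repetition route keeps most of it
  expect_gt(sc$damage_change_pct[sc$scenario == "D"],
            sc$damage_change_pct[sc$scenario == "C"])
  # invariant to the nominal lift count
  sc2 <- productivity_scenarios(nominal_reps = 250)
  expect_equal(sc$damage_change_pct, sc2$damage_change_pct)
})
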
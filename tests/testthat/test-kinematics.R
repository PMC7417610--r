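test_that("leaf elongation rate averages successive daily increments", {
  expect_equal(leaf_elongation_rate(c(0, 24), c(100, 148)), 2.0)
  expect_equal(leaf_elongation_rate(c(0, 24, 48), c(100, 148, 196)), 2.0)
  expect_warning(ler <- leaf_elongation_rate(c(0, 24), c(100, 90)), "decreased")
  expect_lt(ler, 0)
  expect_error(leaf_elongation_rate(0, 100))
})

test_that("cell production rate is LER over mature cell length", {
  expect_equal(cell_production_rate(2.352, 0.147), 16)
  expect_equal(cell_production_rate(0, 0.1), 0)
  expect_error(cell_production_rate(2, 0), "positive")
})

test_that("cell counting is exact on flat and linear profiles", {
  flat <- make_smoothed(0:10, rep(0.02, 11))
  expect_equal(count_cells(flat, 0, 10), 500)
  flat2 <- make_smoothed(0:10, rep(0.1, 11))
  expect_equal(count_cells(flat2, 0, 10), 100)

  # linear 0.02 -> 0.147 over [10, 30]: closed form (b-a)/(l_b-l_a) ln(l_b/l_a)
  grid <- seq(10, 30, by = 1)
  lin <- make_smoothed(grid, 0.02 + (grid - 10) / 20 * 0.127)
  closed <- 20 / 0.127 * log(0.147 / 0.02)
  expect_equal(count_cells(lin, 10, 30), closed, tolerance = 1e-10)

  # off-grid endpoints interpolate; closed form on the sub-interval
  la <- 0.02 + 0.5 / 20 * 0.127
  lb <- 0.02 + 19.5 / 20 * 0.127
  expect_equal(count_cells(lin, 10.5, 29.5), 19 / (lb - la) * log(lb / la),
               tolerance = 1e-10)
  expect_error(count_cells(lin, 5, 30), "beyond")
  expect_error(count_cells(lin, 20, 20), "a < b")
})

test_that("division parameters follow the identity chain", {
  d <- division_params(P = 16, N_mer = 500)
  expect_equal(d$D, 0.032)
  expect_equal(d$T_c, log(2) / 0.032, tolerance = 1e-12)  # 21.66 h
  expect_equal(d$T_mer, log2(500) * d$T_c)                # 194.2 h
  expect_equal(division_params(7, 7)$D, 1)
  expect_equal(division_params(7, 7)$T_c, log(2))
  expect_equal(division_params(log(2) / 20 * 64, 64)$T_mer, 120)
  expect_error(division_params(16, 0), "positive")
})

test_that("kinematic identities hold to machine precision over random draws", {
  set.seed(99)
  for (i in 1:1000) {
    LER <- runif(1, 0.1, 5)
    l_mat <- runif(1, 0.05, 0.3)
    N_mer <- runif(1, 50, 2000)
    N_el <- runif(1, 10, 1000)
    P <- cell_production_rate(LER, l_mat)
    d <- division_params(P, N_mer)
    T_el <- elongation_residence(N_el, P)
    expect_equal(P, LER / l_mat, tolerance = 1e-12)
    expect_equal(d$D * N_mer, P, tolerance = 1e-12)
    expect_equal(d$T_c * d$D, log(2), tolerance = 1e-12)
    expect_equal(d$T_mer, log2(N_mer) * d$T_c, tolerance = 1e-12)
    expect_equal(T_el * P, N_el, tolerance = 1e-12)
  }
})

test_that("flux is a linear ramp capped at the production rate", {
  expect_equal(flux_profile(0, 16, 10), 0)
  expect_equal(flux_profile(10, 16, 10), 16)
  expect_equal(flux_profile(5, 16, 10), 8)
  expect_equal(flux_profile(c(50, 100), 16, 10), c(16, 16))
})

test_that("velocity is the pointwise product of cell length and flux", {
  grid <- 0:20
  Fx <- flux_profile(grid, P = 20, L_mer = 10)
  v <- velocity_profile(rep(0.05, 21), Fx)
  expect_equal(v[grid == 0], 0)
  expect_equal(v[grid == 5], 0.5)
  expect_equal(v[grid == 10], 20 * 0.05)
})

test_that("RGR profile differentiates velocity on the grid", {
  grid <- 0:50
  expect_equal(rgr_length_profile(0.04 * grid, grid), rep(0.04, 51))
  expect_equal(rgr_length_profile(rep(2, 51), grid), rep(0, 51))
  expect_error(rgr_length_profile(1:5, c(0, 1, 3, 4, 5)), "uniform")
})

test_that("RGR profile matches the analytic derivative of the simulator velocity", {
  cfg <- sim_config()
  m <- growth_zone_model(cfg)
  grid <- seq(0, 60, by = 1)
  v <- m$v(grid)
  d <- rgr_length_profile(v, grid)
  # derivative undefined exactly at the two kinks; exclude those grid points
  keep <- !(grid %in% c(cfg$L_mer, cfg$L_gz[["length"]]))
  expect_lt(max(abs(d - m$rgr_length(grid))[keep]), 1e-8)
})

test_that("integrated RGR balances the velocity gain (conservation)", {
  cfg <- sim_config()
  m <- growth_zone_model(cfg)
  grid <- seq(0, 40, by = 1)
  d <- rgr_length_profile(m$v(grid), grid)
  gain <- sum((d[-1] + d[-length(d)]) / 2)  # trapezoid, unit spacing
  expect_equal(gain, m$v(40) - m$v(0), tolerance = 0.01 * m$v(40))
  expect_equal(m$v(40), unname(ground_truth(cfg)$LER))
})

test_that("zone RGR modes agree on their defining examples", {
  expect_equal(zone_rgr(10, 20, 10, mode = "log"), log(2) / 10)
  expect_equal(zone_rgr(5, 5, 3, mode = "log"), 0)
  expect_equal(zone_rgr(5, 5, 3, mode = "difference"), 0)
  expect_equal(zone_rgr(5, 5, 3, mode = "simple-relative"), 0)
  expect_equal(zone_rgr(10, 25, 5, mode = "difference"), 3)
  expect_equal(zone_rgr(10, 25, 5, mode = "simple-relative"), 0.3)
  expect_error(zone_rgr(10, 20, 0), "dt")
  expect_error(zone_rgr(-1, 20, 5, mode = "log"), "positive")
})

test_that("log-mode zone RGR is antisymmetric under swapping sizes", {
  set.seed(4)
  for (i in 1:50) {
    s <- runif(2, 1, 200)
    dt <- runif(1, 1, 100)
    expect_equal(zone_rgr(s[1], s[2], dt), -zone_rgr(s[2], s[1], dt))
  }
})

test_that("elongation-zone width RGR matches trajectory-averaged growth", {
  # along a material trajectory, d log(w)/dt = rgr_width(x(t)); the zone
  # average log(w2/w1)/T_el must equal the time average of rgr_width
  cfg <- sim_config()
  tr <- ground_truth(cfg)
  m <- growth_zone_model(cfg)
  dt <- 0.001
  x <- cfg$L_mer
  t <- 0
  lw <- 0
  while (x < cfg$L_gz[["width"]]) {
    lw <- lw + m$rgr_width(x) * dt
    x <- x + m$v(x) * dt
    t <- t + dt
  }
  expect_equal(log(m$w_mat / cfg$w_base) / t, lw / t, tolerance = 0.01)
  expect_equal(unname(tr$rgr_el["width"]), lw / t, tolerance = 0.02)
})

test_that("anisotropy ratios and their edge cases", {
  expect_equal(unname(anisotropy_ratios(0.06, 0.03, 0.015)), c(2, 4))
  expect_equal(unname(anisotropy_ratios(0.05, 0.05, 0.05)), c(1, 1))
  expect_error(anisotropy_ratios(0, 1, 1), "zero")
})

test_that("percent differences reproduce published-table arithmetic", {
  expect_equal(percent_difference(353, 141), -60)
  expect_equal(percent_difference(13.3, 23.4), 76)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(40, 0), -100)
  expect_equal(percent_difference(4000, 1300), -68)   # -67.5 rounds away from zero
  expect_equal(percent_difference(200, 203), 2)       # 1.5 rounds away from zero
  expect_equal(percent_difference(100, 150, rounded = FALSE), 50)
  expect_error(percent_difference(0, 10), "non-zero")
})
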
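test_that("noise-free sampled profiles equal the analytic model", {
  cfg <- sim_config(n_reps = 1, cv_noise = 0, cells_per_position = 1,
                    length_sd = 0)
  ds <- simulate_growth_zone(cfg, seed = 7)
  m <- ds$model
  pr <- ds$profiles
  expected <- list(
    length.cell = function(x) m$l(x) * 1000,
    width.cell = m$w,
    thickness.cell = m$h,
    width.organ = function(x) cfg$n_files * m$w(x) / 1000,
    thickness.organ = function(x) (1 + cfg$thickness_factor) * m$h(x)
  )
  for (key in names(expected)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- pr[pr$dimension == parts[1] & pr$level == parts[2], ]
    expect_equal(sub$size, expected[[key]](sub$position_mm),
                 tolerance = 1e-6, info = key)
  }
  expect_equal(ds$meristem$L_mer_mm, cfg$L_mer)
  expect_equal(ds$leaf_lengths$length_mm,
               cfg$leaf_length0 + ds$truth$LER * ds$leaf_lengths$time_h)
})

test_that("cell length is continuous at the meristem boundary and reaches l_mat", {
  cfg <- sim_config()
  m <- growth_zone_model(cfg)
  eps <- 1e-9
  expect_equal(m$l(cfg$L_mer - eps), m$l(cfg$L_mer + eps), tolerance = 1e-6)
  x <- seq(0, max(cfg$L_gz) + 20, by = 0.1)
  expect_true(all(diff(m$l(x)) >= -1e-12))
  expect_equal(m$l(cfg$L_gz[["length"]]), cfg$l_mat, tolerance = 1e-6)
  # velocity boundary values
  expect_equal(m$v(0), 0)
  expect_equal(m$v(cfg$L_mer), cfg$P * cfg$l_div)
  expect_equal(m$v(max(cfg$L_gz) + 50), cfg$P * cfg$l_mat)
})

test_that("ground truth satisfies the kinematic identity chain", {
  tr <- ground_truth(sim_config())
  expect_equal(tr$P, tr$LER / 0.147)
  expect_equal(tr$N_mer, 10 / 0.02)   # L_mer / l_div = 500
  expect_equal(tr$D, tr$P / tr$N_mer)
  expect_equal(tr$T_c, log(2) / tr$D)
  expect_equal(tr$T_mer, log2(tr$N_mer) * tr$T_c)
  expect_equal(tr$T_el_model, tr$N_el_model / tr$P)
  expect_equal(unname(tr$LER), 16 * 0.147)  # = 2.352 mm/h
})

test_that("elongation residence time matches material-point trajectory integration", {
  cfg <- sim_config()
  tr <- ground_truth(cfg)
  t_traj <- trajectory_time(tr$v, cfg$L_mer, cfg$L_gz[["length"]], dt = 0.001)
  expect_equal(t_traj, tr$T_el_model[["length"]], tolerance = 0.01)
})

test_that("zero anisotropy gives flat width and height profiles", {
  cfg <- sim_config(aniso_w = 0, aniso_h = 0, n_reps = 1, cv_noise = 0,
                    cells_per_position = 1)
  ds <- simulate_growth_zone(cfg, seed = 1)
  w <- ds$profiles[ds$profiles$dimension == "width" & ds$profiles$level == "cell", ]
  h <- ds$profiles[ds$profiles$dimension == "thickness" & ds$profiles$level == "cell", ]
  expect_equal(w$size, rep(cfg$w_base, nrow(w)))
  expect_equal(h$size, rep(cfg$h_base, nrow(h)))
})

test_that("degenerate config without elongation growth collapses the growth zone", {
  cfg <- sim_config(l_div = 0.1, l_mat = 0.1)
  m <- growth_zone_model(cfg)
  tr <- ground_truth(cfg)
  x <- seq(0, 100, by = 1)
  expect_equal(m$l(x), rep(0.1, length(x)))
  expect_equal(m$rgr_length(5), unname(0.1 * cfg$P / cfg$L_mer))
  expect_equal(m$rgr_length(15), 0)
  expect_equal(unname(tr$L_gz_model["length"]), cfg$L_mer)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(l_div = 0.2, l_mat = 0.1), "mature")
  expect_error(sim_config(L_mer = 40, L_gz = 30), "L_mer")
  expect_error(sim_config(P = -1), "positive")
  expect_error(sim_config(cv_noise = -0.1), "cv_noise")
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_growth_zone(sim_config(n_reps = 2), seed = 42)
  b <- simulate_growth_zone(sim_config(n_reps = 2), seed = 42)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$leaf_lengths, b$leaf_lengths)
})

test_that("section image phantom has exact band geometry and determinism", {
  g <- generate_section_image(thickness_px = 3, n_segments = 6,
                              signal_mean = 90, noise_mean = 10,
                              noise_sd = 0, image_size = 256, seed = 5)
  img <- g$image
  col <- g$probe$from[2]
  profile_vals <- img[, col]
  expect_equal(sum(profile_vals > 50), 6 * 3)  # 6 bands x 3 px along the probe
  # bands are contiguous runs of exactly 3
  runs <- rle(profile_vals > 50)
  expect_equal(sum(runs$values), 6)
  expect_true(all(runs$lengths[runs$values] == 3))
  # noiseless background is exactly noise_mean
  expect_true(all(img[img < 50] == 10))

  g2 <- generate_section_image(3, 6, 90, 10, noise_sd = 2, image_size = 256, seed = 5)
  g3 <- generate_section_image(3, 6, 90, 10, noise_sd = 2, image_size = 256, seed = 5)
  expect_identical(unclass(g2$image), unclass(g3$image))

  expect_error(generate_section_image(thickness_px = 50, n_segments = 6,
                                      image_size = 256), "fit")
})

test_that("leaf images round-trip through 16-bit TIFF", {
  g <- generate_section_image(3, 6, 90, 10, noise_sd = 0, image_size = 64,
                              pixel_size = 39)
  path <- tempfile(fileext = ".tif")
  write_leaf_image(g$image, path, max_intensity = 100)
  back <- read_leaf_image(path, pixel_size = 39, max_intensity = 100)
  expect_equal(unclass(back), unclass(g$image), tolerance = 1 / 2^12,
               ignore_attr = TRUE)
  unlink(path)
})
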
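test_that("grid construction follows the fixed band-count and center convention", {
  g <- make_grid(400, 1000, 2.35)
  expect_equal(n_bands(g), 255L)
  expect_equal(g$centers[1], 401.175)
  expect_equal(g$centers[2] - g$centers[1], 2.35)
  expect_equal(n_bands(make_grid(400, 402.35, 2.35)), 1L)
  expect_error(make_grid(400, 1000, 0), "step")
  expect_error(make_grid(500, 400, 2.35), "greater")
})

test_that("boundary-band removal trims one band per side by default", {
  s <- tiny_set(matrix(runif(2 * 255), 2, 255), step = 2.35)
  expect_equal(n_bands(drop_boundary_bands(s)$grid), 253L)
  s3 <- tiny_set(matrix(1:6 / 10, 2, 3))
  trimmed <- drop_boundary_bands(s3, 1)
  expect_equal(n_bands(trimmed$grid), 1L)
  expect_equal(trimmed$grid$centers, s3$grid$centers[2])
  expect_identical(drop_boundary_bands(s3, 0), s3)
  expect_error(drop_boundary_bands(s3, 2), "too few")
})

test_that("black-white correction is the two-point affine map", {
  g <- make_grid(400, 430, 10)
  cal <- calibration_pair(100, 900, rho_dark = 0.05, rho_white = 0.95)
  dn <- spectrum_set(matrix(c(100, 900, 500), 1), g, domain = "dn")
  rho <- calibrate_reflectance(dn, cal)$values
  expect_equal(rho[1], 0.05)   # dark anchor
  expect_equal(rho[2], 0.95)   # white anchor
  expect_equal(rho[3], 0.5)    # midpoint linearity
  expect_error(calibration_pair(500, 500), "degenerate")
})

test_that("calibration is strictly monotone in DN", {
  g <- make_grid(400, 420, 2)
  cal <- calibration_pair(10, 1010, rho_dark = 0.02, rho_white = 0.98)
  dn_vals <- matrix(sort(runif(10, 10, 1010)), 1)
  rho <- calibrate_reflectance(spectrum_set(dn_vals, g, domain = "dn"), cal)
  expect_true(all(diff(as.vector(rho$values)) > 0))
})

test_that("DN simulation round-trips through calibration", {
  ds <- default_dataset(3, n_samples = 8)
  scene <- simulate_dn_scene(ds, gain = 2000, offset = 50, noise_sd_dn = 0)
  back <- calibrate_reflectance(scene$dn, scene$cal)
  expect_equal(back$values, ds$spectra$values, tolerance = 1e-12)

  # identity parameters: DN equals reflectance
  scene1 <- simulate_dn_scene(ds, gain = 1, offset = 0)
  expect_equal(scene1$dn$values, ds$spectra$values)
  expect_equal(scene1$cal$dn_dark, 0)
  expect_equal(scene1$cal$dn_white, 1)

  expect_error(simulate_dn_scene(ds, gain = -1), "gain")
})

test_that("noisy DN round-trip error is bounded by the sensor noise", {
  ds <- default_dataset(4, n_samples = 30, noise_sd_additive = 0,
                        noise_sd_multiplicative = 0)
  gain <- 1000; sd_dn <- 5
  scene <- simulate_dn_scene(ds, gain = gain, offset = 0,
                             noise_sd_dn = sd_dn, seed = 9)
  back <- calibrate_reflectance(scene$dn, scene$cal)
  err <- rmse(as.vector(back$values), as.vector(ds$spectra$values))
  expect_lt(err, 3 * sd_dn / gain)
  expect_gt(err, 0)
})

test_that("interval cropping keeps the closed interval and composes", {
  ds <- default_dataset(3, n_samples = 8)
  s <- drop_boundary_bands(ds$spectra)
  cropped <- crop_interval(s, 400, 800)
  expect_true(all(cropped$grid$centers >= 400 & cropped$grid$centers <= 800))
  # count by direct enumeration of the convention
  expect_equal(n_bands(cropped$grid),
               sum(s$grid$centers >= 400 & s$grid$centers <= 800))
  # full-range crop is the identity
  full <- crop_interval(s, s$grid$centers[1], s$grid$centers[253])
  expect_equal(full$values, s$values)
  # nested crops collapse to the inner interval
  expect_equal(crop_interval(crop_interval(s, 450, 900), 500, 700)$values,
               crop_interval(s, 500, 700)$values)
  expect_error(crop_interval(s, 1500, 1600), "no band")
})
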
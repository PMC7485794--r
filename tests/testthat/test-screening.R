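test_that("per-band Pearson association handles exact and null relationships", {
  chl <- c(-2, -1, 0, 1, 2) + 50
  vals <- cbind(chl / 100, (100 - chl) / 100, (chl - 50)^2 / 100)
  s <- tiny_set(vals, chl = chl)
  p <- pearson_per_band(s)
  expect_equal(unname(p[1]), 1)
  expect_equal(unname(p[2]), -1)
  expect_equal(unname(p[3]), 0, tolerance = 1e-12)  # symmetric quadratic
  expect_error(pearson_per_band(tiny_set(vals, chl = rep(1, 5))), "constant")
})

test_that("Pearson is invariant to positive affine transforms", {
  set.seed(2)
  chl <- runif(30, 10, 90)
  x <- 0.2 + 0.003 * chl + rnorm(30, 0, 0.01)
  s1 <- tiny_set(cbind(x), chl = chl)
  s2 <- tiny_set(cbind(0.1 + 0.5 * x), chl = 3 + 2 * chl)
  expect_equal(pearson_per_band(s1, chl), pearson_per_band(s2, 3 + 2 * chl))
})

test_that("distance correlation matches the V-statistic oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x <- runif(5); y <- runif(5)
    expect_equal(dcor(x, y), dcor_oracle(x, y), tolerance = 1e-12)
  }
  # identical variables: dcor 1
  z <- runif(8)
  expect_equal(dcor(z, z), 1)
  # quadratic on symmetric support: Pearson blind, dcor not
  chl <- c(-2, -1, 0, 1, 2)
  expect_equal(dcor_oracle(chl, chl^2), dcor(chl, chl^2), tolerance = 1e-12)
  expect_gt(dcor(chl, chl^2), 0.3)
  expect_equal(abs(cor(chl, chl^2)), 0, tolerance = 1e-12)
})

test_that("distance correlation of independent draws stays small", {
  set.seed(123)
  x <- runif(300); y <- runif(300)
  expect_lt(dcor(x, y), 0.15)
  # affine invariance of the estimator
  expect_equal(dcor(2 * x + 1, -3 * y + 5), dcor(x, y), tolerance = 1e-10)
})

test_that("MIC finds functional structure and ignores noise", {
  set.seed(11)
  x <- sort(runif(100, 0, 1))
  expect_equal(mic_score(x, x^3 + 2), 1, tolerance = 1e-9)     # monotone
  expect_equal(mic_score(x, -5 * x + 1), 1, tolerance = 1e-9)  # linear
  # monotone invariance: same value under strictly increasing transforms
  expect_equal(mic_score(exp(x), log(x + 1)), mic_score(x, x),
               tolerance = 1e-9)
  set.seed(12)
  a <- runif(200); b <- runif(200)
  expect_lt(mic_score(a, b), 0.25)
})

test_that("MIC of the 2x2 checkerboard identity is exactly 1", {
  # four points with y = x: the 2x2 grid gives MI = 1 bit, normalized 1
  x <- c(0, 0, 1, 1)
  y <- c(0, 0, 1, 1)
  expect_equal(mic_score(x, y), 1)
})

test_that("parabolic dependence is visible to MIC but not Pearson", {
  set.seed(13)
  t <- runif(120, -1, 1)
  y <- t^2
  expect_lt(abs(cor(t, y)), 0.2)
  expect_gt(mic_score(t, y), 0.6)
})

test_that("screening vectors align and peak at the planted band", {
  # dip depth must stay above the clipping floor (gain * chl_max < shelf),
  # otherwise saturation at zero reflectance moves the correlation peak to
  # the dip flanks
  cfg <- synthetic_config(n_samples = 120, seed = 21,
                          absorption_centers = 550,
                          absorption_widths = 15,
                          absorption_gains = 4e-4,
                          red_edge_shift = 0,
                          noise_sd_additive = 0.002,
                          noise_sd_multiplicative = 0)
  ds <- generate_dataset(cfg)
  s <- crop_interval(ds$spectra, 400, 800)
  res <- screen_bands(s)
  expect_equal(nrow(res), n_bands(s$grid))
  expect_true(all(res$dcor >= 0 & res$dcor <= 1))
  expect_true(all(res$mic >= 0 & res$mic <= 1))
  peaks <- attr(res, "peak_band")
  # all three methods agree on the single informative wavelength
  expect_true(all(abs(peaks - 550) < 15), info = paste(peaks, collapse = ", "))
  expect_error(mic_per_band(tiny_set(matrix(runif(9), 9, 1),
                                     chl = runif(9))), "10 samples")
})
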
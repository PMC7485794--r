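test_that("generation is deterministic and respects truncation bounds", {
  cfg <- synthetic_config(n_samples = 40, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$spectra$values, b$spectra$values)
  expect_identical(a$chl_true, b$chl_true)
  expect_true(all(a$chl_true >= cfg$chl_min & a$chl_true <= cfg$chl_max))
  expect_true(all(a$spectra$values >= 0 & a$spectra$values <= 1))
  expect_equal(a$planted_bands, c(430, 670, 700))
})

test_that("chlorophyll sample mean matches the field-campaign target", {
  cfg <- synthetic_config(n_samples = 500, seed = 7)
  ds <- generate_dataset(cfg)
  # truncation at [2.6, 99.7] pulls the SD below the parent's 26.94
  se <- sd(ds$chl_true) / sqrt(500)
  expect_lt(abs(mean(ds$chl_true) - 54.66), 3 * se)
  stats <- summarize_chl(ds$chl_true)
  expect_gt(stats$cv_percent, 40)  # high-dispersion field conditions
})

test_that("the noise-free forward model depends on chlorophyll alone", {
  # squeeze the truncation window so all draws are (near-)equal chlorophyll:
  # without noise, the spectra must collapse onto one curve
  cfg <- synthetic_config(n_samples = 6, seed = 9, noise_sd_additive = 0,
                          noise_sd_multiplicative = 0, chl_mean = 50,
                          chl_sd = 1e-8, chl_min = 49, chl_max = 51)
  ds <- generate_dataset(cfg)
  expect_lt(max(apply(ds$spectra$values, 2, sd)), 1e-8)
})

test_that("reflectance at an absorption center decreases strictly with chlorophyll", {
  cfg <- synthetic_config(n_samples = 50, seed = 8, noise_sd_additive = 0,
                          noise_sd_multiplicative = 0)
  ds <- generate_dataset(cfg)
  ord <- order(ds$chl_true)
  for (center in cfg$absorption_centers) {
    band <- which.min(abs(ds$spectra$grid$centers - center))
    vals <- ds$spectra$values[ord, band]
    expect_true(all(diff(vals) < 0), info = paste(center, "nm"))
  }
})

test_that("a signal-free generator yields flat association", {
  cfg <- synthetic_config(n_samples = 80, seed = 12,
                          absorption_gains = c(0, 0), red_edge_shift = 0,
                          noise_sd_additive = 0, noise_sd_multiplicative = 0)
  ds <- generate_dataset(cfg)
  # all spectra identical regardless of chlorophyll
  expect_equal(max(apply(ds$spectra$values, 2, sd)), 0)
  expect_warning(p <- pearson_per_band(ds$spectra), "constant band")
  expect_true(all(abs(p) < 1e-12))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(chl_min = 100, chl_max = 50), "chl_min")
  expect_error(synthetic_config(n_samples = 0), "n_samples")
  expect_error(synthetic_config(absorption_widths = c(-1, 5)),
               "absorption_widths")
  expect_error(synthetic_config(noise_sd_additive = -0.1),
               "noise_sd_additive")
})

test_that("dataset writer emits the spectra table and a provenance config", {
  ds <- default_dataset(3, n_samples = 5)
  dir <- file.path(tempdir(), "synth_out")
  paths <- write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  cfg_back <- yaml::read_yaml(paths["config"])
  expect_equal(cfg_back$n_samples, 5)
  expect_equal(cfg_back$grid$step, 2.35)
})
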
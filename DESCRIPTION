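Package: chlospec
Title: Canopy Chlorophyll Inversion from Hyperspectral Reflectance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end inversion of rice canopy chlorophyll content (mg/L)
    from visible/near-infrared hyperspectral reflectance. Provides raw
    digital-number to reflectance calibration against dark/white reference
    panels, wavelength-grid handling and a minimal ENVI cube reader,
    Savitzky-Golay spectral smoothing and per-band signal-to-noise ratios,
    single-band association screening (Pearson, distance correlation, maximal
    information coefficient), characteristic-band extraction by the
    successive projections algorithm with exhaustive multiple-linear-
    regression subset refinement, extreme learning machine regression with
    particle-swarm-optimized input layers, orthogonal-array (L25) tuning of
    the swarm hyperparameters with marginal-sum analysis, and a seeded
    synthetic canopy-spectra generator so the whole pipeline is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
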
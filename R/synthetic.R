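#' Configuration of the synthetic canopy-spectra generator
#'
#' Describes the seeded forward model used to emulate japonica-rice canopy
#' reflectance over 400--1000 nm with chlorophyll-dependent structure:
#' a low visible shelf rising through a logistic red edge to a NIR plateau,
#' Gaussian absorption dips whose depths grow linearly with chlorophyll, a
#' red-edge inflection that shifts to longer wavelengths with chlorophyll,
#' and multiplicative plus additive Gaussian noise. Default chlorophyll
#' statistics match a field campaign of 196 rice canopy samples
#' (mean 54.66, SD 26.94, range 2.60--99.70 mg/L).
#'
#' @param n_samples number of samples to draw.
#' @param chl_mean,chl_sd mean and SD (mg/L) of the underlying normal
#'   chlorophyll distribution.
#' @param chl_min,chl_max truncation bounds (mg/L), `chl_min < chl_max`.
#' @param grid wavelength grid of the simulated sensor.
#' @param absorption_centers centers (nm) of pigment absorption dips.
#' @param absorption_widths Gaussian widths (nm) of the dips, all `> 0`.
#' @param absorption_gains dip depth per unit chlorophyll (reflectance units
#'   per mg/L), one per center.
#' @param red_edge_base red-edge inflection wavelength at zero chlorophyll
#'   (nm).
#' @param red_edge_shift inflection shift per unit chlorophyll (nm per mg/L).
#' @param red_edge_width logistic width of the red edge (nm).
#' @param vis_shelf visible-range baseline reflectance.
#' @param nir_plateau NIR plateau reflectance.
#' @param noise_sd_additive additive noise SD (reflectance units).
#' @param noise_sd_multiplicative multiplicative noise SD (fraction).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 196L,
                             chl_mean = 54.66, chl_sd = 26.94,
                             chl_min = 2.60, chl_max = 99.70,
                             grid = make_grid(400, 1000, 2.35),
                             absorption_centers = c(430, 670),
                             absorption_widths = c(40, 28),
                             absorption_gains = c(4e-4, 4e-4),
                             red_edge_base = 700,
                             red_edge_shift = 0.08,
                             red_edge_width = 16,
                             vis_shelf = 0.05,
                             nir_plateau = 0.45,
                             noise_sd_additive = 0.002,
                             noise_sd_multiplicative = 0.01,
                             seed = 1L) {
  bad <- function(field, msg) {
    stop(sprintf("invalid synthetic config: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 1) bad("n_samples", "must be >= 1")
  if (!is.numeric(chl_sd) || chl_sd <= 0) bad("chl_sd", "must be > 0")
  if (chl_min >= chl_max) bad("chl_min", "must be smaller than `chl_max`")
  if (!inherits(grid, "wavelength_grid")) bad("grid", "must be a wavelength_grid")
  k <- length(absorption_centers)
  if (length(absorption_widths) != k || length(absorption_gains) != k) {
    bad("absorption_widths", "and `absorption_gains` must match the centers")
  }
  if (k > 0 && any(absorption_widths <= 0)) bad("absorption_widths", "must be > 0")
  if (k > 0 && any(absorption_gains < 0)) bad("absorption_gains", "must be >= 0")
  if (red_edge_width <= 0) bad("red_edge_width", "must be > 0")
  if (noise_sd_additive < 0) bad("noise_sd_additive", "must be >= 0")
  if (noise_sd_multiplicative < 0) bad("noise_sd_multiplicative", "must be >= 0")
  if (!(vis_shelf >= 0 && nir_plateau <= 1 && vis_shelf < nir_plateau)) {
    bad("vis_shelf", "and `nir_plateau` must satisfy 0 <= shelf < plateau <= 1")
  }
  structure(
    list(n_samples = as.integer(n_samples), chl_mean = chl_mean,
         chl_sd = chl_sd, chl_min = chl_min, chl_max = chl_max, grid = grid,
         absorption_centers = absorption_centers,
         absorption_widths = absorption_widths,
         absorption_gains = absorption_gains,
         red_edge_base = red_edge_base, red_edge_shift = red_edge_shift,
         red_edge_width = red_edge_width, vis_shelf = vis_shelf,
         nir_plateau = nir_plateau, noise_sd_additive = noise_sd_additive,
         noise_sd_multiplicative = noise_sd_multiplicative,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Truncated-normal draws by rejection sampling (exact).
rtruncnorm_reject <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# Noise-free forward model: reflectance matrix for a chlorophyll vector.
clean_spectra <- function(cfg, chl) {
  lambda <- cfg$grid$centers
  n <- length(chl)
  edge_pos <- cfg$red_edge_base + cfg$red_edge_shift * chl
  base <- cfg$vis_shelf + (cfg$nir_plateau - cfg$vis_shelf) *
    stats::plogis(outer(-edge_pos, lambda, `+`) / cfg$red_edge_width)
  for (i in seq_along(cfg$absorption_centers)) {
    dip_shape <- exp(-(lambda - cfg$absorption_centers[i])^2 /
                       (2 * cfg$absorption_widths[i]^2))
    base <- base - (cfg$absorption_gains[i] * chl) %o% dip_shape
  }
  base
}

#' Generate a synthetic canopy dataset
#'
#' Draws chlorophyll from a truncated normal (rejection sampling), evaluates
#' the deterministic reflectance model of [synthetic_config()], applies
#' multiplicative then additive Gaussian noise, and clips to the physical
#' range `[0, 1]`.
#'
#' @param cfg a [synthetic_config()].
#' @return An object of class `synthetic_dataset`: `spectra` (a
#'   `spectrum_set` carrying the chlorophyll targets), `chl_true` (mg/L),
#'   `planted_bands` (nm; the chlorophyll-informative wavelengths the
#'   generator actually used: absorption centers and red-edge base) and the
#'   generating `config`.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_samples = 20, seed = 7))
#' range(ds$chl_true)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  local_seed(cfg$seed, {
    chl <- rtruncnorm_reject(cfg$n_samples, cfg$chl_mean, cfg$chl_sd,
                             cfg$chl_min, cfg$chl_max)
    refl <- clean_spectra(cfg, chl)
    if (cfg$noise_sd_multiplicative > 0) {
      refl <- refl * (1 + matrix(
        stats::rnorm(length(refl), 0, cfg$noise_sd_multiplicative),
        nrow = nrow(refl)))
    }
    if (cfg$noise_sd_additive > 0) {
      refl <- refl + matrix(
        stats::rnorm(length(refl), 0, cfg$noise_sd_additive),
        nrow = nrow(refl))
    }
    refl <- pmin(pmax(refl, 0), 1)
    spectra <- spectrum_set(refl, cfg$grid, chl = chl, domain = "reflectance")
    structure(
      list(spectra = spectra, chl_true = chl,
           planted_bands = c(cfg$absorption_centers, cfg$red_edge_base),
           config = cfg),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d samples, chlorophyll %.2f-%.2f mg/L, planted bands: %s nm\n",
    length(x$chl_true), min(x$chl_true), max(x$chl_true),
    paste(x$planted_bands, collapse = ", ")
  ))
  invisible(x)
}

#' Simulate a raw-DN acquisition of a synthetic dataset
#'
#' Maps reflectance to sensor digital numbers, `DN = gain * rho + offset +`
#' Gaussian sensor noise, and builds the matching dark/white calibration
#' panel pair (panel DN are recorded noise-free at `gain * rho + offset`),
#' so that [calibrate_reflectance()] round-trips the scene.
#'
#' @param ds a `synthetic_dataset` (or a reflectance `spectrum_set`).
#' @param gain DN per reflectance unit, `> 0`.
#' @param offset DN offset.
#' @param rho_dark,rho_white panel reflectivities.
#' @param noise_sd_dn sensor noise SD in DN (default 0).
#' @param seed RNG seed for the sensor noise.
#' @return A list with `dn` (DN-domain `spectrum_set`) and `cal`
#'   (a [calibration_pair()]).
#' @export
simulate_dn_scene <- function(ds, gain = 1000, offset = 100,
                              rho_dark = 0, rho_white = 1,
                              noise_sd_dn = 0, seed = 1L) {
  s <- if (inherits(ds, "synthetic_dataset")) ds$spectra else ds
  stopifnot(inherits(s, "spectrum_set"))
  if (s$domain != "reflectance") {
    stop("input spectra must be in the reflectance domain", call. = FALSE)
  }
  assert_scalar_number(gain, "gain", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd_dn, "noise_sd_dn", lower = 0)
  dn_vals <- local_seed(seed, {
    v <- gain * s$values + offset
    if (noise_sd_dn > 0) {
      v <- v + matrix(stats::rnorm(length(v), 0, noise_sd_dn), nrow = nrow(v))
    }
    v
  })
  cal <- calibration_pair(
    dn_dark = gain * rho_dark + offset,
    dn_white = gain * rho_white + offset,
    rho_dark = rho_dark, rho_white = rho_white
  )
  dn <- spectrum_set(dn_vals, s$grid, sample_ids = s$sample_ids, chl = s$chl,
                     domain = "dn")
  list(dn = dn, cal = cal)
}

#' Write a synthetic dataset plus provenance config
#'
#' Writes the spectra table (see [write_spectra_table()]) and a YAML file
#' recording the full generator configuration alongside it.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @param name file stem (default `"synthetic"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir, name = "synthetic") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spectra_path <- file.path(dir, paste0(name, "_spectra.tsv"))
  config_path <- file.path(dir, paste0(name, "_config.yaml"))
  write_spectra_table(ds$spectra, spectra_path)
  cfg <- ds$config
  cfg_list <- unclass(cfg)
  cfg_list$grid <- list(start = cfg$grid$start, end = cfg$grid$end,
                        step = cfg$grid$step)
  yaml::write_yaml(cfg_list, config_path)
  invisible(c(spectra = spectra_path, config = config_path))
}
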
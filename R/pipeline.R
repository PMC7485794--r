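# End-to-end orchestration: synthetic scene (or ingested table) -> DN
# calibration -> boundary/interval trimming -> smoothing -> screening ->
# SPA band selection -> modeling/validation split -> (optional) orthogonal
# tuning -> PSO-ELM inversion -> evaluation.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    synthetic = list(),                   # overrides for synthetic_config()
    dn = list(enabled = TRUE, gain = 1000, offset = 100, noise_sd_dn = 0,
              rho_dark = 0, rho_white = 1),
    boundary_bands = 1L,
    interval = c(400, 800),
    smoothing = list(window_length = 11L, polyorder = 3L),
    screening = list(enabled = TRUE,
                     methods = c("pearson", "dcor", "mic"), alpha = 0.6),
    spa = list(n_select = 10L, max_refine = 12L, k_folds = 5L),
    split = list(frac_model = 0.84, n_strata = 5L),
    tuning = list(enabled = FALSE, iterations = 25L),
    model = list(hidden_count = 20L,
                 pso = list(pop = 50L, w = c(0.9, 0.3), c1 = 1.65, c2 = 2.8,
                            m = 0.2, iterations = 100L))
  )
}

merge_config <- function(defaults, overrides, path = "") {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) {
    stop(sprintf("config section `%s` must be a list", path), call. = FALSE)
  }
  nm <- names(overrides)
  if (length(overrides) > 0 && (is.null(nm) || any(nm == ""))) {
    stop(sprintf("config section `%s` has unnamed entries", path),
         call. = FALSE)
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, ".", unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in nm) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Assemble a validated pipeline configuration
#'
#' Starts from the package defaults and applies the supplied overrides;
#' unknown keys are rejected, so typos fail loudly instead of being
#' silently ignored. The `synthetic` section takes any argument of
#' [synthetic_config()] except `seed`, which (like every stage seed) is
#' derived from the master `seed` through named substreams. The default
#' swarm parameters are the working set selected by the bundled orthogonal
#' tuning experiment (`pop = 50`, `w = 0.9~0.3`, `c1 = 1.65`, `c2 = 2.8`,
#' `m = 0.2`; see [reference_orthogonal_runs()]).
#'
#' @param ... named overrides of the default sections (`seed`, `synthetic`,
#'   `dn`, `boundary_bands`, `interval`, `smoothing`, `screening`, `spa`,
#'   `split`, `tuning`, `model`).
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, synthetic = list(n_samples = 60),
#'                        screening = list(enabled = FALSE))
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- merge_config(pipeline_defaults(), overrides, "config")
  structure(cfg, class = "pipeline_config")
}

#' Run the full chlorophyll-inversion pipeline
#'
#' Executes, in order: synthetic scene generation; DN simulation and
#' black-white calibration (optional); boundary-band removal and interval
#' cropping; Savitzky-Golay smoothing; modeling/validation split; per-band
#' association screening (optional); SPA candidate selection with MLR
#' subset refinement on the modeling set; orthogonal-array tuning of the
#' swarm (optional) or the configured swarm parameters; PSO-ELM fitting
#' with a plain-ELM baseline; and validation-set evaluation. All
#' stage seeds are derived from the master seed, so a rerun with the same
#' configuration is bit-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate
#'   artifact (spectra tables, screening table, band selection, models,
#'   report, resolved config) is written there.
#' @return An object of class `pipeline_result`: `report` (PSO-ELM,
#'   validation), `elm_report` (baseline), `refinement`, `screening`,
#'   `snr_db`, `split`, `models`, `tuning`, and the resolved `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  master <- cfg$seed

  # --- scene -------------------------------------------------------------
  syn_args <- cfg$synthetic
  syn_args$seed <- derive_seed(master, "synthetic")
  scfg <- do.call(synthetic_config, syn_args)
  ds <- generate_dataset(scfg)
  spectra <- ds$spectra

  if (isTRUE(cfg$dn$enabled)) {
    scene <- simulate_dn_scene(
      ds, gain = cfg$dn$gain, offset = cfg$dn$offset,
      rho_dark = cfg$dn$rho_dark, rho_white = cfg$dn$rho_white,
      noise_sd_dn = cfg$dn$noise_sd_dn, seed = derive_seed(master, "dn")
    )
    spectra <- calibrate_reflectance(scene$dn, scene$cal)
  }

  # --- trim + smooth -----------------------------------------------------
  spectra <- drop_boundary_bands(spectra, cfg$boundary_bands)
  spectra <- crop_interval(spectra, cfg$interval[1L], cfg$interval[2L])
  smoothed <- savgol_smooth(
    spectra, smoothing_config(cfg$smoothing$window_length,
                              cfg$smoothing$polyorder)
  )
  snr <- band_snr(smoothed)

  # --- split -------------------------------------------------------------
  split <- split_dataset(smoothed, frac_model = cfg$split$frac_model,
                         seed = derive_seed(master, "split"),
                         n_strata = cfg$split$n_strata)
  modeling <- split$modeling
  validation <- split$validation

  # --- screening (modeling set only; validation stays untouched) ---------
  screening <- NULL
  if (isTRUE(cfg$screening$enabled)) {
    screening <- screen_bands(modeling, methods = cfg$screening$methods,
                              alpha = cfg$screening$alpha)
  }

  # --- SPA + MLR refinement ---------------------------------------------
  candidates <- spa_select_bands(modeling, n_select = cfg$spa$n_select)
  refine_idx <- candidates$indices[
    seq_len(min(length(candidates$indices), cfg$spa$max_refine))]
  refinement <- mlr_refine(modeling, candidate_indices = refine_idx,
                           k_folds = cfg$spa$k_folds,
                           seed = derive_seed(master, "cv"))
  band_idx <- refinement$refined_indices

  X_train <- modeling$values[, band_idx, drop = FALSE]
  y_train <- modeling$chl
  X_val <- validation$values[, band_idx, drop = FALSE]
  y_val <- validation$chl

  # --- swarm parameters: tuned or configured ------------------------------
  tuning <- NULL
  pso_par <- cfg$model$pso
  if (isTRUE(cfg$tuning$enabled)) {
    design <- build_l25_design()
    r2_runs <- run_orthogonal_experiment(
      X_train, y_train, X_val, y_val, design,
      hidden_count = cfg$model$hidden_count,
      iterations = cfg$tuning$iterations,
      seed = derive_seed(master, "doe")
    )
    marg <- marginal_analysis(design, r2_runs)
    tuning <- list(design = design, r2 = r2_runs, marginal = marg)
    bv <- marg$best_values
    pso_par <- list(pop = bv$pop, w = bv$w, c1 = bv$c1, c2 = bv$c2,
                    m = bv$m, iterations = pso_par$iterations)
  }

  # --- models ------------------------------------------------------------
  pso_cfg <- pso_config(pop = pso_par$pop, w = pso_par$w, c1 = pso_par$c1,
                        c2 = pso_par$c2, m = pso_par$m,
                        iterations = pso_par$iterations,
                        seed = derive_seed(master, "pso"))
  pso_model <- pso_elm_fit(X_train, y_train, X_val, y_val,
                           hidden_count = cfg$model$hidden_count,
                           cfg = pso_cfg)
  elm_model <- elm_fit(X_train, y_train,
                       hidden_count = cfg$model$hidden_count,
                       seed = derive_seed(master, "elm"))

  report <- evaluate_predictions(y_val, elm_predict(pso_model, X_val),
                                 validation$sample_ids)
  elm_report <- evaluate_predictions(y_val, elm_predict(elm_model, X_val),
                                     validation$sample_ids)

  result <- structure(
    list(report = report, elm_report = elm_report, refinement = refinement,
         screening = screening, snr_db = snr, split = split,
         models = list(pso_elm = pso_model, elm = elm_model),
         tuning = tuning, dataset = ds, config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== chlorophyll inversion pipeline ==\n")
  cat(sprintf("bands refined: %s nm\n",
              paste(round(x$refinement$refined_subset, 2), collapse = ", ")))
  cat(sprintf("PSO-ELM  validation R^2 = %.3f, RMSE = %.3f mg/L\n",
              x$report$r2, x$report$rmse))
  cat(sprintf("ELM      validation R^2 = %.3f, RMSE = %.3f mg/L\n",
              x$elm_report$r2, x$elm_report$rmse))
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_table(result$split$modeling,
                      file.path(out_dir, "modeling_spectra.tsv"))
  write_spectra_table(result$split$validation,
                      file.path(out_dir, "validation_spectra.tsv"))
  if (!is.null(result$screening)) {
    utils::write.table(as.data.frame(result$screening),
                       file.path(out_dir, "screening.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(selected_wavelengths = result$refinement$selected_wavelengths,
         refined_subset = result$refinement$refined_subset,
         refined_cv_rmse = result$refinement$refined_rmse),
    file.path(out_dir, "band_selection.json"),
    digits = NA, auto_unbox = TRUE
  )
  write_elm_json(result$models$pso_elm, file.path(out_dir, "pso_elm.json"))
  write_elm_json(result$models$elm, file.path(out_dir, "elm.json"))
  jsonlite::write_json(
    list(pso_elm = list(r2 = result$report$r2, rmse = result$report$rmse,
                        n = result$report$n),
         elm = list(r2 = result$elm_report$r2, rmse = result$elm_report$rmse,
                    n = result$elm_report$n)),
    file.path(out_dir, "report.json"), digits = NA, auto_unbox = TRUE
  )
  utils::write.table(result$report$predictions,
                     file.path(out_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result$config
  cfg$screening$methods <- as.list(cfg$screening$methods)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
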
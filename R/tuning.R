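# L25(5^5) orthogonal-array tuning of the PSO hyperparameters, with
# Taguchi-style marginal-sum analysis: W[i, j] sums the response (run R^2)
# over the five runs where factor j sits at level i, and the per-factor
# argmax picks the working parameter set without a full 5^5 sweep.

#' Default PSO factor levels for the L25 tuning experiment
#'
#' Five levels for each of the five swarm hyperparameters: population size,
#' inertia weight (constants and linear schedules), learning factors C1 and
#' C2, and the velocity-position coefficient m.
#'
#' @return Named list of five level vectors/lists (`pop`, `w`, `c1`, `c2`,
#'   `m`); `w` levels 4 and 5 are the schedules `0.9~0.3` and `0.3~1.5`.
#' @export
default_pso_levels <- function() {
  list(
    pop = list(40L, 50L, 60L, 70L, 80L),
    w = list(0.3, 0.9, 1.5, c(0.9, 0.3), c(0.3, 1.5)),
    c1 = list(1.1, 1.3, 1.65, 2.8, 3.5),
    c2 = list(1.1, 1.3, 1.65, 2.8, 3.5),
    m = list(0.02, 0.06, 0.2, 0.6, 1)
  )
}

#' Build an L25(5^5) orthogonal design
#'
#' Canonical Galois-field construction: writing each run as `r = 5a + b + 1`
#' with `a, b` in `0..4`, the level indices are `pop = a`, `w = b`,
#' `c1 = (a + b) mod 5`, `c2 = (2a + b) mod 5`, `m = (3a + b) mod 5`
#' (all 1-based in the result). Every factor level occurs in exactly 5 runs
#' and every ordered pair of factors sees all 25 level combinations exactly
#' once.
#'
#' @param levels named list of exactly 5 factors with 5 levels each
#'   (default [default_pso_levels()]).
#' @return An object of class `orthogonal_design`: `factors` (names),
#'   `levels`, and `runs`, a 25 x 5 matrix of 1-based level indices.
#' @export
build_l25_design <- function(levels = default_pso_levels()) {
  if (length(levels) != 5L || is.null(names(levels)) ||
      any(lengths(levels) != 5L)) {
    stop("need exactly 5 named factors with 5 levels each", call. = FALSE)
  }
  a <- rep(0:4, each = 5L)
  b <- rep(0:4, times = 5L)
  runs <- cbind(
    a,
    b,
    (a + b) %% 5L,
    (2L * a + b) %% 5L,
    (3L * a + b) %% 5L
  ) + 1L
  colnames(runs) <- names(levels)
  rownames(runs) <- paste0("run", 1:25)
  structure(list(factors = names(levels), levels = levels, runs = runs),
            class = "orthogonal_design")
}

#' Marginal-sum analysis of an orthogonal experiment
#'
#' Computes the 5 x 5 marginal table `W`, where `W[i, j]` is the sum of the
#' response over the five runs with factor `j` at level `i`, and selects the
#' best level of each factor as the row of maximum `W`. Since every column
#' partitions the same 25 runs, `colSums(W)` equals the total response sum
#' for every factor (conservation). Ties are broken toward the lowest level
#' index with a warning.
#'
#' @param design an `orthogonal_design`.
#' @param r2 numeric vector of 25 finite per-run responses (validation R^2),
#'   aligned to the design's run order.
#' @return An object of class `marginal_table`: `W`, `best_level` (1-based
#'   indices per factor) and `best_values` (the corresponding level values).
#' @export
marginal_analysis <- function(design, r2) {
  stopifnot(inherits(design, "orthogonal_design"))
  r2 <- as.numeric(r2)
  if (length(r2) != 25L || any(!is.finite(r2))) {
    stop("need 25 finite response values", call. = FALSE)
  }
  W <- matrix(0, 5L, 5L, dimnames = list(paste0("level", 1:5),
                                         design$factors))
  for (j in seq_len(5L)) {
    W[, j] <- vapply(1:5, function(i) sum(r2[design$runs[, j] == i]),
                     numeric(1))
  }
  best <- integer(5L)
  for (j in seq_len(5L)) {
    top <- which(W[, j] >= max(W[, j]) - 1e-12)
    if (length(top) > 1L) {
      warning(sprintf("tie among levels {%s} of factor `%s`; taking the lowest",
                      paste(top, collapse = ", "), design$factors[j]))
    }
    best[j] <- top[1L]
  }
  names(best) <- design$factors
  best_values <- lapply(seq_len(5L), function(j) design$levels[[j]][[best[j]]])
  names(best_values) <- design$factors
  structure(list(W = W, best_level = best, best_values = best_values),
            class = "marginal_table")
}

#' @export
print.marginal_table <- function(x, ...) {
  print(round(x$W, 3))
  cat("best levels:",
      paste(sprintf("%s=%s", names(x$best_level),
                    vapply(x$best_values, function(v)
                      paste(v, collapse = "~"), character(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Run the 25 tuning experiments of an orthogonal design
#'
#' Trains one PSO-ELM per design run with that run's parameter levels and
#' records the validation R^2. Per-run seeds are derived deterministically
#' from the master seed, so runs are independent yet reproducible.
#'
#' @param X,y training data; `X_val,y_val` validation data.
#' @param design an `orthogonal_design` over `pop`, `w`, `c1`, `c2`, `m`.
#' @param hidden_count ELM hidden nodes.
#' @param iterations PSO iterations per run (default 100).
#' @param seed master seed.
#' @return Numeric vector of 25 validation R^2 values.
#' @export
run_orthogonal_experiment <- function(X, y, X_val, y_val, design,
                                      hidden_count = 20L, iterations = 100L,
                                      seed = 1L) {
  stopifnot(inherits(design, "orthogonal_design"))
  needed <- c("pop", "w", "c1", "c2", "m")
  if (!all(needed %in% design$factors)) {
    stop("design must cover factors pop, w, c1, c2, m", call. = FALSE)
  }
  vapply(seq_len(25L), function(r) {
    lv <- function(f) design$levels[[f]][[design$runs[r, f]]]
    cfg <- pso_config(
      pop = lv("pop"), w = lv("w"), c1 = lv("c1"), c2 = lv("c2"),
      m = lv("m"), iterations = iterations,
      seed = derive_seed(seed, paste0("doe_run", r))
    )
    model <- pso_elm_fit(X, y, X_val, y_val, hidden_count = hidden_count,
                         cfg = cfg)
    r2_score(y_val, elm_predict(model, as.matrix(X_val)))
  }, numeric(1))
}

#' Reference orthogonal tuning experiment
#'
#' A published 25-run L25(5^5) tuning experiment of PSO-ELM on
#' field-measured rice canopy data, bundled as package data: the factor
#' levels of every run and the validation R^2 it achieved. Feeding its `r2`
#' column through [marginal_analysis()] reproduces the marginal sums and
#' the selected working parameters (`pop = 50`, `w = 0.9~0.3`, `c1 = 1.65`,
#' `c2 = 2.8`, `m = 0.2`).
#'
#' @return Data frame with columns `run`, `pop`, `w` (schedules written
#'   `start~end`), `c1`, `c2`, `m`, `r2`.
#' @export
reference_orthogonal_runs <- function() {
  path <- system.file("extdata", "pso_orthogonal_reference.csv",
                      package = "chlospec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
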
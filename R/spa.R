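# Successive projections algorithm: forward wavelength selection that
# minimizes collinearity. At each step every still-unselected column is
# replaced by its residual after orthogonal projection onto the complement
# of the last selected vector, and the column with the largest remaining
# l2 norm is taken next.

#' Successive projections algorithm column selection
#'
#' Given an `M x J` calibration matrix whose columns are candidate
#' wavelengths, selects `N` columns of minimum mutual collinearity. The
#' first selection is the column of largest l2 norm; each subsequent step
#' projects all unselected (already residualized) columns into the null
#' space of the previously selected vector,
#' \deqn{e_j = y_j - z_{k-1} (z_{k-1}^T z_{k-1})^{-1} z_{k-1}^T y_j,}
#' selects the largest-norm residual, and keeps the residuals for the next
#' iteration. Selection stops early, with a warning, if all residual norms
#' fall below the numerical floor `1e-12`.
#'
#' @param X numeric matrix (`M` calibration spectra by `J` candidate
#'   wavelengths); no all-zero matrix.
#' @param N number of columns to select, `1 <= N <= min(M, J)`.
#' @return Integer vector of selected column indices in selection order,
#'   with attribute `history`: a list, one element per iteration, holding
#'   the residual l2 norms of the then-unselected columns (named by column
#'   index).
#' @examples
#' X <- cbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
#' spa_select(X, 3)  # 3, 2, 1 - decreasing norm among orthogonal columns
#' @export
spa_select <- function(X, N) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    stop("calibration matrix must be finite", call. = FALSE)
  }
  M <- nrow(X); J <- ncol(X)
  N <- as.integer(N)
  if (N < 1L || N > min(M, J)) {
    stop("`N` must lie in 1..min(rows, columns)", call. = FALSE)
  }
  if (all(X == 0)) stop("calibration matrix is all zero", call. = FALSE)

  floor_norm <- 1e-12
  Y <- X
  S <- seq_len(J)
  A <- integer(0)
  history <- vector("list", N)

  for (k in seq_len(N)) {
    norms <- sqrt(colSums(Y[, S, drop = FALSE]^2))
    names(norms) <- S
    history[[k]] <- norms
    if (max(norms) < floor_norm) {
      warning("all residual norms below the numerical floor; returning ",
              length(A), " of ", N, " requested selections")
      history <- history[seq_len(k - 1L)]
      break
    }
    a_k <- S[which.max(norms)]
    A <- c(A, a_k)
    S <- setdiff(S, a_k)
    if (length(S) == 0L || k == N) next
    z <- Y[, a_k]
    denom <- sum(z * z)
    coef <- crossprod(z, Y[, S, drop = FALSE]) / denom   # 1 x |S|
    Y[, S] <- Y[, S, drop = FALSE] - z %*% coef
  }
  structure(A, history = history[seq_along(history)])
}

#' Exhaustive MLR refinement of a candidate band subset
#'
#' Fits an ordinary least squares model of chlorophyll on every nonempty
#' subset of the candidate bands (plus intercept) and scores each subset by
#' K-fold cross-validated RMSE; the subset with the smallest CV-RMSE wins.
#' Ties (within relative tolerance `1e-10`) are broken by smaller subset
#' size, then lexicographic index order. Subsets whose design matrix is
#' singular inside any fold score `+Inf`.
#'
#' @param s a `spectrum_set` (reflectance matrix supplies the columns).
#' @param chl chlorophyll vector (defaults to `s$chl`).
#' @param candidate_indices band indices from [spa_select()]; at most 15.
#' @param k_folds number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param folds optional explicit fold assignment (integer vector in
#'   `1..k_folds`, one per sample) overriding the seeded draw.
#' @return An object of class `spa_refinement`: `selected_wavelengths` (all
#'   candidates, nm), `selected_indices`, `refined_subset` (nm),
#'   `refined_indices`, `refined_rmse` (mg/L) and `subset_table` (every
#'   subset with its CV-RMSE).
#' @export
mlr_refine <- function(s, chl = NULL, candidate_indices, k_folds = 5L,
                       seed = 1L, folds = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  chl <- check_chl_arg(s, chl)
  candidate_indices <- as.integer(candidate_indices)
  p <- length(candidate_indices)
  if (p < 1L || p > 15L) {
    stop("between 1 and 15 candidate bands are supported", call. = FALSE)
  }
  if (anyDuplicated(candidate_indices)) {
    stop("candidate indices must be distinct", call. = FALSE)
  }
  n <- n_samples(s)
  k_folds <- as.integer(k_folds)
  if (k_folds < 2L || k_folds > n) {
    stop("`k_folds` must lie in 2..n", call. = FALSE)
  }
  if (is.null(folds)) {
    folds <- local_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  }
  stopifnot(length(folds) == n)

  X_all <- s$values[, candidate_indices, drop = FALSE]
  subsets <- lapply(seq_len(2^p - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
  })
  # order by size then lexicographic member order so that ties resolve to
  # the smallest, earliest subset
  ord <- order(lengths(subsets),
               vapply(subsets, function(ss) {
                 sum(2^(p - ss)) # lexicographic rank
               }, numeric(1)))
  subsets <- subsets[ord]

  cv_rmse_subset <- function(cols) {
    sq_err <- numeric(0)
    for (f in seq_len(k_folds)) {
      test <- folds == f
      Xtr <- cbind(1, X_all[!test, cols, drop = FALSE])
      fit <- stats::lm.fit(Xtr, chl[!test])
      if (fit$rank < ncol(Xtr)) return(Inf)
      pred <- cbind(1, X_all[test, cols, drop = FALSE]) %*% fit$coefficients
      sq_err <- c(sq_err, (chl[test] - pred)^2)
    }
    sqrt(mean(sq_err))
  }
  rmses <- vapply(subsets, cv_rmse_subset, numeric(1))

  best_rmse <- min(rmses)
  tied <- which(rmses <= best_rmse + max(abs(best_rmse), 1) * 1e-10)
  best <- tied[1L] # subsets pre-ordered by (size, lexicographic)
  refined_local <- subsets[[best]]

  subset_table <- data.frame(
    subset = vapply(subsets, function(ss) {
      paste(candidate_indices[ss], collapse = "+")
    }, character(1)),
    size = lengths(subsets),
    cv_rmse = rmses
  )
  structure(
    list(
      selected_wavelengths = s$grid$centers[candidate_indices],
      selected_indices = candidate_indices,
      refined_subset = s$grid$centers[candidate_indices[refined_local]],
      refined_indices = candidate_indices[refined_local],
      refined_rmse = rmses[best],
      subset_table = subset_table
    ),
    class = "spa_refinement"
  )
}

#' @export
print.spa_refinement <- function(x, ...) {
  cat(sprintf(
    "<spa_refinement> %d candidates -> %d bands (%s nm), CV-RMSE %.4g mg/L\n",
    length(x$selected_indices), length(x$refined_indices),
    paste(round(x$refined_subset, 2), collapse = ", "), x$refined_rmse
  ))
  invisible(x)
}

#' SPA band selection on a spectrum set
#'
#' Convenience wrapper: runs [spa_select()] on the spectral matrix and
#' reports the selected wavelengths.
#'
#' @param s a `spectrum_set` (typically the smoothed modeling-set
#'   reflectance restricted to the analysis interval).
#' @param n_select number of candidate bands (default 10).
#' @return A list with `indices` (selection order) and `wavelengths` (nm).
#' @export
spa_select_bands <- function(s, n_select = 10L) {
  stopifnot(inherits(s, "spectrum_set"))
  idx <- spa_select(s$values, n_select)
  list(indices = as.integer(idx), wavelengths = s$grid$centers[idx],
       history = attr(idx, "history"))
}
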
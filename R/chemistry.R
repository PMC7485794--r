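#' Chlorophyll content from optical densities
#'
#' Converts spectrophotometer absorbances of the pigment extract at 663 nm
#' and 645 nm to total chlorophyll content:
#' \deqn{Chl\ (mg/L) = 5.134\, OD_{663} + 20.436\, OD_{645}.}
#'
#' @param od663,od645 absorbances at 663 and 645 nm (non-negative;
#'   vectorized).
#' @return Chlorophyll content (mg/L).
#' @examples
#' chl_from_od(0.5, 0.2)  # 6.6542
#' @export
chl_from_od <- function(od663, od645) {
  if (length(od663) != length(od645)) {
    stop("`od663` and `od645` must have the same length", call. = FALSE)
  }
  if (!is.numeric(od663) || !is.numeric(od645) ||
      anyNA(od663) || anyNA(od645)) {
    stop("optical densities must be numeric and non-missing", call. = FALSE)
  }
  if (any(od663 < 0) || any(od645 < 0)) {
    stop("optical densities must be non-negative", call. = FALSE)
  }
  5.134 * od663 + 20.436 * od645
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean`, rounded to 2 decimals as reported in dataset summary
#' tables.
#'
#' @param mean,sd summary statistics; `mean > 0`.
#' @return CV in percent, rounded to 2 decimals.
#' @examples
#' cv_percent(54.33, 27.31)  # 50.27
#' @export
cv_percent <- function(mean, sd) {
  assert_scalar_number(mean, "mean", lower = 0, strict_lower = TRUE)
  assert_scalar_number(sd, "sd", lower = 0)
  round(100 * sd / mean, 2)
}

#' Summary statistics of chlorophyll values
#'
#' Sample statistics used to characterise ground-truth chlorophyll datasets:
#' n, max, min, mean, SD (sample, denominator `n - 1`) and the coefficient
#' of variation in percent (rounded to 2 decimals).
#'
#' @param values numeric chlorophyll values (mg/L), `length >= 2`.
#' @return An object of class `chl_stats`.
#' @export
summarize_chl <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  structure(
    list(n = length(values), max = max(values), min = min(values),
         mean = m, sd = s,
         cv_percent = if (m > 0) cv_percent(m, s) else NA_real_),
    class = "chl_stats"
  )
}

#' @export
print.chl_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d | min %.2f | max %.2f | mean %.2f | sd %.2f | CV %.2f%%\n",
    x$n, x$min, x$max, round(x$mean, 2), round(x$sd, 2), x$cv_percent
  ))
  invisible(x)
}

#' Split a dataset into modeling and validation sets
#'
#' Draws a seeded modeling/validation partition of size
#' `round(frac_model * n)` / remainder. The split is stratified by
#' chlorophyll quintile so both sets span the full concentration range
#' (per-stratum counts deviate from exact proportionality by at most one
#' sample, allocated by largest remainder). Falls back to a simple random
#' split, with a warning, when the sample is too small to stratify.
#'
#' @param s a `spectrum_set` with chlorophyll targets.
#' @param frac_model fraction assigned to the modeling set, in (0, 1);
#'   default 0.84 (196 samples split 165/31).
#' @param seed RNG seed.
#' @param n_strata number of chlorophyll strata (default 5 = quintiles).
#' @return A list with `modeling` and `validation` spectrum sets; together
#'   they partition the input.
#' @export
split_dataset <- function(s, frac_model = 0.84, seed = 1L, n_strata = 5L) {
  stopifnot(inherits(s, "spectrum_set"))
  if (is.null(s$chl)) stop("spectrum set carries no chlorophyll", call. = FALSE)
  assert_scalar_number(frac_model, "frac_model", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (frac_model >= 1) stop("`frac_model` must be < 1", call. = FALSE)
  n <- n_samples(s)
  n_model <- round(frac_model * n)
  if (n_model < 1L || n_model >= n) {
    stop("degenerate split: one side would be empty", call. = FALSE)
  }

  local_seed(seed, {
    strata <- rep(1L, n)
    use_strata <- n >= 2L * n_strata
    if (use_strata) {
      qs <- stats::quantile(s$chl, probs = seq(0, 1, length.out = n_strata + 1))
      strata <- cut(s$chl, breaks = unique(qs), include.lowest = TRUE,
                    labels = FALSE)
      if (length(unique(strata)) < 2L) use_strata <- FALSE
    }
    if (!use_strata) {
      warning("too few samples (or degenerate chlorophyll) for stratification; ",
              "using a simple random split")
      model_idx <- sample.int(n, n_model)
    } else {
      counts <- tabulate(strata)
      exact <- frac_model * counts
      take <- floor(exact)
      short <- n_model - sum(take)
      if (short > 0) {
        extra <- order(exact - take, decreasing = TRUE)[seq_len(short)]
        take[extra] <- take[extra] + 1L
      } else if (short < 0) {
        # trim from the smallest remainders
        cut_from <- order(exact - take)[seq_len(-short)]
        take[cut_from] <- take[cut_from] - 1L
      }
      model_idx <- unlist(lapply(seq_along(counts), function(b) {
        members <- which(strata == b)
        if (take[b] >= length(members)) members
        else members[sample.int(length(members), take[b])]
      }))
    }
    model_idx <- sort(model_idx)
    list(
      modeling = subset_samples(s, model_idx),
      validation = subset_samples(s, setdiff(seq_len(n), model_idx))
    )
  })
}
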
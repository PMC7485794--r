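#' Savitzky-Golay smoothing configuration
#'
#' @param window_length odd number of bands in the moving window; must be at
#'   least `polyorder + 2`.
#' @param polyorder degree of the local least-squares polynomial.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(window_length = 11L, polyorder = 3L) {
  window_length <- as.integer(window_length)
  polyorder <- as.integer(polyorder)
  if (window_length %% 2L != 1L) {
    stop("`window_length` must be odd", call. = FALSE)
  }
  if (polyorder < 0L || window_length < polyorder + 2L) {
    stop("`window_length` must be at least `polyorder + 2`", call. = FALSE)
  }
  structure(list(window_length = window_length, polyorder = polyorder),
            class = "smoothing_config")
}

# Dense n x n smoothing matrix: row i holds the filter evaluated at band i.
# Interior rows share the centered least-squares coefficients; near the
# boundaries the window is truncated one-sided and a polynomial of degree
# min(polyorder, window size - 1) is fitted to whatever bands remain.
savgol_matrix <- function(n, window_length, polyorder) {
  h <- (window_length - 1L) %/% 2L
  S <- matrix(0, n, n)
  fit_row <- function(offsets, at) {
    p <- min(polyorder, length(offsets) - 1L)
    A <- outer(offsets, 0:p, `^`)
    # row of the hat matrix for evaluation point `at`
    as.vector(outer(at, 0:p, `^`) %*% solve(crossprod(A), t(A)))
  }
  center_coef <- fit_row((-h):h, 0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      S[i, lo:hi] <- center_coef
    } else {
      S[i, lo:hi] <- fit_row((lo:hi) - i, 0)
    }
  }
  S
}

#' Savitzky-Golay convolution smoothing of spectra
#'
#' Smooths every sample's spectrum with a moving least-squares polynomial
#' filter. Interior bands use the standard centered filter; boundary bands
#' are fitted on the truncated one-sided window (degree reduced when fewer
#' points than `polyorder + 1` remain). The filter reproduces polynomials of
#' degree `<= polyorder` exactly and is linear in the input.
#'
#' @param s a `spectrum_set`.
#' @param cfg a [smoothing_config()] (default window 11, order 3 --
#'   conventional for ~2.35 nm band spacing).
#' @return The smoothed `spectrum_set` (reflectance clipped to `[0, 1]`).
#' @export
savgol_smooth <- function(s, cfg = smoothing_config()) {
  stopifnot(inherits(s, "spectrum_set"), inherits(cfg, "smoothing_config"))
  nb <- n_bands(s$grid)
  if (cfg$window_length > nb) {
    stop("smoothing window exceeds the number of bands", call. = FALSE)
  }
  S <- savgol_matrix(nb, cfg$window_length, cfg$polyorder)
  sm <- s$values %*% t(S)
  if (s$domain == "reflectance") sm <- pmin(pmax(sm, 0), 1)
  spectrum_set(sm, s$grid, sample_ids = s$sample_ids, chl = s$chl,
               domain = s$domain)
}

#' Per-band signal-to-noise ratio
#'
#' For each band, the ratio of the total signal power to the signal variance
#' across samples, in decibels:
#' \deqn{SNR_{dB} = 10 \log_{10}( \overline{x^2} / \mathrm{var}(x) )}
#' with the population variance (denominator `n`). Bands with zero variance
#' report `+Inf`. A pooled summary over all bands is attached as attribute
#' `"pooled_db"`.
#'
#' @param s a `spectrum_set` with at least 2 samples.
#' @return Numeric vector of per-band SNR (dB), named by band center, with
#'   attribute `pooled_db`.
#' @examples
#' g <- make_grid(400, 406, 3)
#' s <- spectrum_set(matrix(c(1, 0, 0.6, 0, 1, 1), 2, 3), g)
#' band_snr(s)
#' @export
band_snr <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  x <- s$values
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  ms <- colMeans(x^2)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2            # population variance
  v <- pmax(v, 0)                      # guard tiny negative round-off
  snr <- ifelse(v == 0, Inf, 10 * log10(ms / v))
  names(snr) <- format(s$grid$centers, trim = TRUE, digits = 8)
  pooled_v <- mean((x - matrix(mu, nrow(x), ncol(x), byrow = TRUE))^2)
  attr(snr, "pooled_db") <- if (pooled_v == 0) Inf else
    10 * log10(mean(ms) / pooled_v)
  snr
}
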
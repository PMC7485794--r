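# Single-band association screening: how strongly does each wavelength's
# reflectance track chlorophyll? Pearson captures linear association,
# distance correlation arbitrary dependence, and MIC grid-detectable
# (including non-monotone) functional structure.

check_chl_arg <- function(s, chl) {
  if (is.null(chl)) chl <- s$chl
  if (is.null(chl)) stop("no chlorophyll vector supplied", call. = FALSE)
  chl <- as.numeric(chl)
  if (length(chl) != n_samples(s)) {
    stop("chlorophyll length does not match the sample count", call. = FALSE)
  }
  chl
}

#' Per-band Pearson correlation with chlorophyll
#'
#' @param s a `spectrum_set`.
#' @param chl chlorophyll vector (defaults to `s$chl`); must be nonconstant,
#'   `n >= 3`.
#' @return Numeric vector in `[-1, 1]`, one value per band. Constant bands
#'   report 0 with a warning.
#' @export
pearson_per_band <- function(s, chl = NULL) {
  chl <- check_chl_arg(s, chl)
  if (length(chl) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(chl) == 0) stop("chlorophyll is constant", call. = FALSE)
  sds <- apply(s$values, 2L, stats::sd)
  out <- rep(0, n_bands(s$grid))
  ok <- sds > 0
  if (any(!ok)) {
    warning("constant band(s) encountered; reporting association 0")
  }
  if (any(ok)) {
    out[ok] <- as.vector(stats::cor(s$values[, ok, drop = FALSE], chl))
  }
  names(out) <- format(s$grid$centers, trim = TRUE, digits = 8)
  out
}

#' Distance correlation of two samples
#'
#' Classical (biased, V-statistic) distance correlation from doubly centered
#' Euclidean pairwise-distance matrices. Lies in `[0, 1]`; 0 for constant
#' input.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return Distance correlation.
#' @export
dcor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  A <- dcenter(abs(outer(x, x, `-`)))
  B <- dcenter(abs(outer(y, y, `-`)))
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) return(0)
  dcov2 <- mean(A * B)
  r2 <- dcov2 / sqrt(dvar_x * dvar_y)
  sqrt(max(r2, 0))
}

dcenter <- function(D) {
  rm_ <- rowMeans(D)
  gm <- mean(D)
  D - outer(rm_, rep(1, ncol(D))) - outer(rep(1, nrow(D)), colMeans(D)) + gm
}

#' Per-band distance correlation with chlorophyll
#'
#' @inheritParams pearson_per_band
#' @return Numeric vector in `[0, 1]`; constant bands report 0. Requires
#'   `n >= 4`.
#' @export
dcor_per_band <- function(s, chl = NULL) {
  chl <- check_chl_arg(s, chl)
  if (length(chl) < 4L) stop("need at least 4 samples", call. = FALSE)
  B <- dcenter(abs(outer(chl, chl, `-`)))
  dvar_y <- mean(B * B)
  out <- apply(s$values, 2L, function(x) {
    A <- dcenter(abs(outer(x, x, `-`)))
    dvar_x <- mean(A * A)
    if (dvar_x <= 0 || dvar_y <= 0) return(0)
    sqrt(max(mean(A * B) / sqrt(dvar_x * dvar_y), 0))
  })
  names(out) <- format(s$grid$centers, trim = TRUE, digits = 8)
  out
}

#' Maximal information coefficient of two samples
#'
#' Grid-partition dependence measure in `[0, 1]`. This is a bounded-grid
#' approximation of MIC: for every grid shape `r x c` with
#' `r * c <= max(4, floor(n^alpha))`, one axis is equipartitioned (equal
#' frequency) and the cut points of the other are optimized by dynamic
#' programming; mutual information is normalized by `log2(min(r, c))` and
#' the maximum over shapes and both orientations is returned.
#'
#' @param x,y numeric vectors of equal length `>= 4`.
#' @param alpha grid-cell bound exponent, `B(n) = n^alpha` (default 0.6).
#' @return Approximate MIC in `[0, 1]`.
#' @export
mic_score <- function(x, y, alpha = 0.6) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  assert_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  n <- length(x)
  B <- max(4L, as.integer(floor(n^alpha + 1e-9)))
  mic_cpp(as.numeric(x), as.numeric(y), B)
}

#' Per-band maximal information coefficient with chlorophyll
#'
#' @inheritParams pearson_per_band
#' @param alpha grid-cell bound exponent (see [mic_score()]).
#' @return Numeric vector in `[0, 1]`; constant bands report 0. Requires
#'   `n >= 10` (the estimator is unreliable below that).
#' @export
mic_per_band <- function(s, chl = NULL, alpha = 0.6) {
  chl <- check_chl_arg(s, chl)
  if (length(chl) < 10L) stop("need at least 10 samples", call. = FALSE)
  out <- apply(s$values, 2L, function(x) {
    if (max(x) == min(x)) return(0)
    mic_score(x, chl, alpha = alpha)
  })
  names(out) <- format(s$grid$centers, trim = TRUE, digits = 8)
  out
}

#' Screen all bands with all three association measures
#'
#' @inheritParams pearson_per_band
#' @param methods subset of `c("pearson", "dcor", "mic")`.
#' @param alpha MIC grid-cell bound exponent.
#' @return An object of class `screening_result`: a data frame
#'   (`wavelength_nm` plus one column per method) with attribute
#'   `peak_band`, the wavelength of maximum |association| per method.
#' @export
screen_bands <- function(s, chl = NULL,
                         methods = c("pearson", "dcor", "mic"),
                         alpha = 0.6) {
  methods <- match.arg(methods, several.ok = TRUE)
  chl <- check_chl_arg(s, chl)
  tab <- data.frame(wavelength_nm = s$grid$centers)
  peak <- numeric(0)
  if ("pearson" %in% methods) {
    tab$pearson <- unname(pearson_per_band(s, chl))
    peak["pearson"] <- tab$wavelength_nm[which.max(abs(tab$pearson))]
  }
  if ("dcor" %in% methods) {
    tab$dcor <- unname(dcor_per_band(s, chl))
    peak["dcor"] <- tab$wavelength_nm[which.max(tab$dcor)]
  }
  if ("mic" %in% methods) {
    tab$mic <- unname(mic_per_band(s, chl, alpha = alpha))
    peak["mic"] <- tab$wavelength_nm[which.max(tab$mic)]
  }
  structure(tab, peak_band = peak, class = c("screening_result", "data.frame"))
}

#' Plot a screening result
#'
#' Association against wavelength, one curve per method (|Pearson| is shown
#' so all curves share the `[0, 1]` axis).
#'
#' @param x a `screening_result`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.screening_result <- function(x, ...) {
  cols <- setdiff(names(x), "wavelength_nm")
  y <- as.matrix(x[cols])
  if ("pearson" %in% cols) y[, "pearson"] <- abs(y[, "pearson"])
  graphics::matplot(x$wavelength_nm, y, type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "association", ...)
  graphics::legend("topleft", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}
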
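# Small fixtures and independent oracles shared across test files.

# Spectrum set on a tiny grid from an explicit matrix.
tiny_set <- function(values, start = 400, step = 10, chl = NULL,
                     domain = "reflectance") {
  values <- as.matrix(values)
  g <- make_grid(start, start + ncol(values) * step, step)
  spectrum_set(values, g, chl = chl, domain = domain)
}

# Independent step-by-step SPA oracle: literal projection updates with no
# shared code with spa_select (explicit per-column loops, qr-free algebra).
spa_oracle <- function(X, N) {
  J <- ncol(X)
  S <- seq_len(J)
  A <- integer(0)
  Y <- X
  for (k in seq_len(N)) {
    norms <- vapply(S, function(j) sqrt(sum(Y[, j]^2)), numeric(1))
    a_k <- S[which.max(norms)]
    A <- c(A, a_k)
    S <- setdiff(S, a_k)
    if (length(S) > 0 && k < N) {
      z <- Y[, a_k]
      for (j in S) {
        Y[, j] <- Y[, j] - z * sum(z * Y[, j]) / sum(z * z)
      }
    }
  }
  A
}

# Brute-force distance correlation via the raw V-statistic sums
# (S1/S2/S3 formulation), independent of the double-centering route.
dcor_oracle <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, `-`))
  b <- abs(outer(y, y, `-`))
  vsum <- function(a, b) {
    s1 <- sum(a * b) / n^2
    s2 <- sum(a) * sum(b) / n^4
    s3 <- sum(rowSums(a) * rowSums(b)) / n^3
    s1 + s2 - 2 * s3
  }
  v_xy <- vsum(a, b)
  v_xx <- vsum(a, a)
  v_yy <- vsum(b, b)
  if (v_xx <= 0 || v_yy <= 0) return(0)
  sqrt(max(v_xy, 0) / sqrt(v_xx * v_yy))
}

# Default-conditions synthetic dataset, cached per seed for the session.
default_dataset <- local({
  cache <- list()
  function(seed = 101, ...) {
    key <- paste0(seed, "|", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_dataset(synthetic_config(seed = seed, ...))
    }
    cache[[key]]
  }
})

# Smoothed 400-800 nm reflectance + 84/16 split, the standard model input.
prepared_split <- function(ds, seed = 5) {
  s <- crop_interval(drop_boundary_bands(ds$spectra), 400, 800)
  split_dataset(savgol_smooth(s), frac_model = 0.84, seed = seed)
}
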
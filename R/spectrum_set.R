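#' Create a spectrum set
#'
#' The central container: a samples-by-bands matrix of per-wavelength values
#' on a shared grid, flagged as reflectance or raw digital numbers (DN),
#' optionally carrying per-sample chlorophyll ground truth (mg/L).
#'
#' @param values numeric matrix, rows = samples, columns = bands.
#' @param grid a [make_grid()] `wavelength_grid`; column count must match.
#' @param sample_ids optional character ids (default `"s1"`, `"s2"`, ...).
#' @param chl optional numeric vector of chlorophyll content (mg/L).
#' @param domain `"reflectance"` (values in `[0, 1]`) or `"dn"`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(values, grid, sample_ids = NULL, chl = NULL,
                         domain = c("reflectance", "dn")) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(inherits(grid, "wavelength_grid"))
  if (ncol(values) != n_bands(grid)) {
    stop("column count does not match the grid band count", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("spectral values must be finite", call. = FALSE)
  }
  if (domain == "reflectance" &&
      (min(values) < -1e-9 || max(values) > 1 + 1e-9)) {
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  stopifnot(length(sample_ids) == nrow(values))
  if (!is.null(chl)) {
    chl <- as.numeric(chl)
    stopifnot(length(chl) == nrow(values))
  }
  structure(
    list(values = values, grid = grid, sample_ids = as.character(sample_ids),
         chl = chl, domain = domain),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "<spectrum_set> %d samples x %d bands (%s), %.1f-%.1f nm%s\n",
    nrow(x$values), n_bands(x$grid), x$domain,
    x$grid$centers[1L], x$grid$centers[n_bands(x$grid)],
    if (is.null(x$chl)) "" else ", with chlorophyll targets"
  ))
  invisible(x)
}

#' Number of samples in a spectrum set
#' @param s a `spectrum_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  nrow(s$values)
}

# Subset samples (rows), keeping grid and domain.
subset_samples <- function(s, idx) {
  spectrum_set(
    s$values[idx, , drop = FALSE], s$grid,
    sample_ids = s$sample_ids[idx],
    chl = if (is.null(s$chl)) NULL else s$chl[idx],
    domain = s$domain
  )
}

# Subset bands (columns); idx must be a contiguous run so the grid stays
# evenly spaced.
subset_bands <- function(s, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("no bands retained", call. = FALSE)
  if (any(diff(idx) != 1L)) {
    stop("band subset must be contiguous", call. = FALSE)
  }
  spectrum_set(
    s$values[, idx, drop = FALSE],
    grid_from_centers(s$grid$centers[idx], step = s$grid$step),
    sample_ids = s$sample_ids, chl = s$chl, domain = s$domain
  )
}

#' Write a spectrum set as a delimited table
#'
#' One row per sample; columns named `wavelength_nm_<center>` plus, when
#' ground truth is attached, `chl_mg_per_L`. This is the plain-text exchange
#' format consumed by every stage of the pipeline.
#'
#' @param s a `spectrum_set`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(s, path, sep = "\t") {
  stopifnot(inherits(s, "spectrum_set"))
  df <- as.data.frame(s$values)
  names(df) <- paste0("wavelength_nm_", format(s$grid$centers, trim = TRUE,
                                               digits = 10))
  df <- cbind(sample_id = s$sample_ids, df)
  if (!is.null(s$chl)) df$chl_mg_per_L <- s$chl
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum set from a delimited table
#'
#' @param path file written by [write_spectra_table()].
#' @param sep field separator.
#' @param domain value domain flag of the stored spectra.
#' @return A `spectrum_set`.
#' @export
read_spectra_table <- function(path, sep = "\t",
                               domain = c("reflectance", "dn")) {
  domain <- match.arg(domain)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  wcols <- grep("^wavelength_nm_", names(df))
  if (length(wcols) == 0L) stop("no wavelength columns found", call. = FALSE)
  centers <- as.numeric(sub("^wavelength_nm_", "", names(df)[wcols]))
  chl <- if ("chl_mg_per_L" %in% names(df)) df[["chl_mg_per_L"]] else NULL
  ids <- if ("sample_id" %in% names(df)) df[["sample_id"]] else NULL
  spectrum_set(as.matrix(df[wcols]), grid_from_centers(centers),
               sample_ids = ids, chl = chl, domain = domain)
}
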
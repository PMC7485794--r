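# Minimal ENVI-style cube I/O: text header + raw binary image, the exchange
# format of push-broom hyperspectral imagers. Supports BSQ/BIL/BIP interleave
# and the common numeric data types; no map info or geo keys.

.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# Parse an ENVI header into a named list; values of the form { a, b, ... }
# (possibly spanning lines) become numeric/character vectors.
read_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt)) stop("not an ENVI header", call. = FALSE)
  txt <- sub("^\\s*ENVI\\s*", "", txt)
  out <- list()
  pat <- "([a-zA-Z ][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*$", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    if (startsWith(val, "{")) {
      val <- trimws(strsplit(gsub("[{}\n]", "", val), ",")[[1]])
      num <- suppressWarnings(as.numeric(val))
      if (!anyNA(num)) val <- num
    }
    out[[gsub(" +", "_", key)]] <- val
  }
  out
}

#' Read a minimal ENVI-style hyperspectral cube
#'
#' @param header_path path to the text header (`*.hdr`); the binary image is
#'   looked up next to it (same name without `.hdr`, or with `.dat`/`.img`).
#' @return A list with `cube` (array `lines x samples x bands`),
#'   `wavelength` (numeric or `NULL`) and the parsed `header`.
#' @export
read_envi_cube <- function(header_path) {
  hdr <- read_envi_header(header_path)
  for (k in c("samples", "lines", "bands", "data_type", "interleave")) {
    if (is.null(hdr[[k]])) stop(sprintf("header misses `%s`", k), call. = FALSE)
  }
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  tp <- .envi_types[[as.character(as.integer(hdr$data_type))]]
  if (is.null(tp)) stop("unsupported ENVI data type", call. = FALSE)
  interleave <- tolower(trimws(hdr$interleave))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("interleave must be one of bsq, bil, bip", call. = FALSE)
  }
  endian <- if (!is.null(hdr$byte_order) && as.integer(hdr$byte_order) == 1L)
    "big" else "little"

  base <- sub("\\.hdr$", "", header_path)
  data_path <- NULL
  for (cand in c(base, paste0(base, ".dat"), paste0(base, ".img"))) {
    if (file.exists(cand) && cand != header_path) { data_path <- cand; break }
  }
  if (is.null(data_path)) stop("binary image file not found", call. = FALSE)

  n <- ns * nl * nb
  raw_vals <- readBin(data_path, what = tp$what, n = n, size = tp$size,
                      signed = tp$signed, endian = endian)
  if (length(raw_vals) != n) stop("image file truncated", call. = FALSE)
  # fastest-varying index first, per interleave
  arr <- switch(interleave,
    bsq = aperm(array(raw_vals, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, dim = c(nb, ns, nl)), c(3, 2, 1))
  )
  wl <- if (!is.null(hdr$wavelength)) as.numeric(hdr$wavelength) else NULL
  list(cube = arr, wavelength = wl, header = hdr)
}

#' Write a minimal ENVI-style cube
#'
#' Companion writer used to exercise the reader and to build small on-disk
#' scenes in examples and tests.
#'
#' @param cube array `lines x samples x bands`.
#' @param base_path path without extension; writes `<base_path>` (binary) and
#'   `<base_path>.hdr` (text header).
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI numeric type code (1, 2, 3, 4, 5 or 12; default 4 =
#'   32-bit float).
#' @param wavelength optional band-center vector written into the header.
#' @return `base_path`, invisibly.
#' @export
write_envi_cube <- function(cube, base_path, interleave = "bsq",
                            data_type = 4L, wavelength = NULL) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  tp <- .envi_types[[as.character(as.integer(data_type))]]
  if (is.null(tp)) stop("unsupported ENVI data type", call. = FALSE)
  d <- dim(cube)  # lines, samples, bands
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube, c(2, 1, 3))),
    bil = as.vector(aperm(cube, c(2, 3, 1))),
    bip = as.vector(aperm(cube, c(3, 2, 1)))
  )
  if (tp$what == "integer") vals <- as.integer(round(vals))
  con <- file(base_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(vals, con, size = tp$size, endian = "little")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0"
  )
  if (!is.null(wavelength)) {
    hdr <- c(hdr, sprintf("wavelength = {%s}",
                          paste(format(wavelength, trim = TRUE, digits = 10),
                                collapse = ", ")))
  }
  writeLines(hdr, paste0(base_path, ".hdr"))
  invisible(base_path)
}

#' Mean spectrum over a region of interest
#'
#' Averages the spectra of all masked pixels of a cube into one spectrum,
#' the per-plot canopy spectrum fed to the inversion model.
#'
#' @param cube array `lines x samples x bands` (e.g. from
#'   [read_envi_cube()]`$cube`).
#' @param mask `lines x samples` matrix of 0/1 (or logical); pixels with a
#'   nonzero value are averaged.
#' @return Numeric vector of per-band means.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  mask <- as.matrix(mask)
  d <- dim(cube)
  if (!all(dim(mask) == d[1:2])) {
    stop("mask dimensions must match the cube's lines x samples", call. = FALSE)
  }
  sel <- which(mask != 0)
  if (length(sel) == 0L) stop("mask selects no pixels", call. = FALSE)
  flat <- matrix(cube, nrow = d[1L] * d[2L], ncol = d[3L])
  colMeans(flat[sel, , drop = FALSE])
}
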
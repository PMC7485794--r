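#' Construct a wavelength grid
#'
#' Builds the band grid used throughout the package. The convention is fixed:
#' the number of bands is `floor((end - start) / step)` and band `k`
#' (0-based) is centred at `start + (k + 0.5) * step`. A 400--1000 nm range
#' at 2.35 nm spacing therefore yields 255 bands, the grid produced by a
#' push-broom imager resampled at 2.35 nm over the visible/NIR range.
#'
#' @param start lower edge of the spectral range (nm).
#' @param end upper edge of the spectral range (nm).
#' @param step band spacing (nm).
#' @return An object of class `wavelength_grid` with fields `start`, `end`,
#'   `step` and the vector of band `centers` (nm).
#' @examples
#' g <- make_grid(400, 1000, 2.35)
#' n_bands(g)        # 255
#' g$centers[1]      # 401.175
#' @export
make_grid <- function(start, end, step) {
  assert_scalar_number(start, "start")
  assert_scalar_number(end, "end")
  assert_scalar_number(step, "step", lower = 0, strict_lower = TRUE)
  if (end <= start) stop("`end` must be greater than `start`", call. = FALSE)
  count <- as.integer(floor((end - start) / step + 1e-9))
  if (count < 1L) stop("range shorter than one band", call. = FALSE)
  centers <- start + (seq_len(count) - 0.5) * step
  structure(
    list(start = start, end = end, step = step, centers = centers),
    class = "wavelength_grid"
  )
}

# Rebuild a grid from an explicit (contiguous, evenly spaced) center vector,
# e.g. after cropping or reading a spectra table.
grid_from_centers <- function(centers, step = NULL) {
  stopifnot(is.numeric(centers), length(centers) >= 1L)
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("band centers must be strictly increasing", call. = FALSE)
  }
  if (is.null(step)) {
    step <- if (length(centers) > 1L) stats::median(diff(centers)) else 1
  }
  structure(
    list(
      start = centers[1L] - step / 2,
      end = centers[length(centers)] + step / 2,
      step = step,
      centers = as.numeric(centers)
    ),
    class = "wavelength_grid"
  )
}

#' Number of bands in a wavelength grid
#' @param grid a `wavelength_grid`.
#' @return Integer band count.
#' @export
n_bands <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  length(grid$centers)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %.3f-%.3f nm, step %.3g nm\n",
    n_bands(x), x$centers[1L], x$centers[length(x$centers)], x$step
  ))
  invisible(x)
}
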
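#' Dark/white calibration panel pair
#'
#' Holds the two-point radiometric reference used for black-white correction:
#' the digital numbers recorded over a dark and a white calibration panel
#' together with the panels' known reflectivities.
#'
#' @param dn_dark DN recorded over the dark panel (DN1).
#' @param dn_white DN recorded over the white panel (DN2).
#' @param rho_dark reflectivity of the dark panel (default 0).
#' @param rho_white reflectivity of the white panel (default 1).
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(dn_dark, dn_white, rho_dark = 0, rho_white = 1) {
  assert_scalar_number(dn_dark, "dn_dark")
  assert_scalar_number(dn_white, "dn_white")
  assert_scalar_number(rho_dark, "rho_dark", lower = 0, upper = 1)
  assert_scalar_number(rho_white, "rho_white", lower = 0, upper = 1)
  if (dn_white == dn_dark) {
    stop("degenerate calibration: dark and white panel DN are equal",
         call. = FALSE)
  }
  if (rho_dark >= rho_white) {
    stop("`rho_dark` must be strictly smaller than `rho_white`", call. = FALSE)
  }
  structure(
    list(dn_dark = as.numeric(dn_dark), dn_white = as.numeric(dn_white),
         rho_dark = rho_dark, rho_white = rho_white),
    class = "calibration_pair"
  )
}

#' Black-white DN-to-reflectance correction
#'
#' Converts raw digital numbers to reflectance by the two-point affine
#' calibration
#' \deqn{\rho_t = \frac{DN_t - DN_1}{DN_2 - DN_1}(\rho_2 - \rho_1) + \rho_1,}
#' where subscripts 1 and 2 refer to the dark and white reference panels.
#' Results are clipped to the physical reflectance range `[0, 1]` (sensor
#' noise can push values marginally outside it).
#'
#' @param dn a DN-domain `spectrum_set`.
#' @param cal a [calibration_pair()].
#' @return A reflectance-domain `spectrum_set`.
#' @examples
#' g <- make_grid(400, 409, 3)
#' dn <- spectrum_set(matrix(c(0, 50, 100), 1), g, domain = "dn")
#' cal <- calibration_pair(0, 100)
#' calibrate_reflectance(dn, cal)$values  # 0, 0.5, 1
#' @export
calibrate_reflectance <- function(dn, cal) {
  stopifnot(inherits(dn, "spectrum_set"), inherits(cal, "calibration_pair"))
  if (dn$domain != "dn") {
    stop("`dn` must be a DN-domain spectrum set", call. = FALSE)
  }
  rho <- (dn$values - cal$dn_dark) / (cal$dn_white - cal$dn_dark) *
    (cal$rho_white - cal$rho_dark) + cal$rho_dark
  rho <- pmin(pmax(rho, 0), 1)
  spectrum_set(rho, dn$grid, sample_ids = dn$sample_ids, chl = dn$chl,
               domain = "reflectance")
}

#' Remove boundary bands
#'
#' Drops `n_each_side` bands at each spectral boundary, where resampling
#' artefacts concentrate; the 255-band 400--1000 nm grid becomes the 253
#' effective bands used for analysis.
#'
#' @param s a `spectrum_set`.
#' @param n_each_side bands to drop at each end (default 1).
#' @return The trimmed `spectrum_set`.
#' @export
drop_boundary_bands <- function(s, n_each_side = 1L) {
  stopifnot(inherits(s, "spectrum_set"))
  n_each_side <- as.integer(n_each_side)
  if (n_each_side < 0L) stop("`n_each_side` must be >= 0", call. = FALSE)
  if (n_each_side == 0L) return(s)
  nb <- n_bands(s$grid)
  if (nb <= 2L * n_each_side) {
    stop("too few bands to drop boundaries", call. = FALSE)
  }
  subset_bands(s, (n_each_side + 1L):(nb - n_each_side))
}

#' Crop a spectrum set to a wavelength interval
#'
#' Retains bands whose centers fall in the closed interval `[lo, hi]`.
#' Chlorophyll-driven reflectance variation concentrates in 400--800 nm, the
#' default analysis interval of the inversion pipeline.
#'
#' @param s a `spectrum_set`.
#' @param lo,hi interval bounds (nm), `lo < hi`.
#' @return The cropped `spectrum_set`.
#' @export
crop_interval <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum_set"))
  assert_scalar_number(lo, "lo")
  assert_scalar_number(hi, "hi")
  if (lo >= hi) stop("`lo` must be smaller than `hi`", call. = FALSE)
  keep <- which(s$grid$centers >= lo & s$grid$centers <= hi)
  if (length(keep) == 0L) {
    stop("no band centers inside the requested interval", call. = FALSE)
  }
  subset_bands(s, keep)
}
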
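#' Spectral wavelength axis
#'
#' Builds the wavelength axis of the imaging spectrometer: `n_bands` equally
#' spaced bands spanning the visible/near-infrared window.  The default (360
#' bands over 391--1010 nm, spacing about 1.724 nm) matches the camera used
#' throughout the package.
#'
#' @param n_bands number of spectral bands (>= 2).
#' @param range length-2 numeric, wavelength limits in nm (ascending).
#' @return numeric vector of strictly increasing wavelengths in nm.
#' @examples
#' wl <- spectral_axis()
#' length(wl)      # 360
#' range(wl)       # 391 1010
#' @export
spectral_axis <- function(n_bands = 360L, range = c(391, 1010)) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 2L) abort("spectral axis needs at least 2 bands, got %d", n_bands)
  if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1])
    abort("wavelength range must be two ascending finite values")
  seq(range[1], range[2], length.out = n_bands)
}

# validate a wavelength axis (strictly increasing, length >= 2)
check_axis <- function(wavelengths) {
  if (length(wavelengths) < 2L || any(!is.finite(wavelengths)) ||
      any(diff(wavelengths) <= 0))
    abort("wavelength axis must be strictly increasing with >= 2 finite values")
  invisible(wavelengths)
}
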
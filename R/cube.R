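#' Hyperspectral DN cube
#'
#' A raw digital-number (DN) image stack: height x width x n_bands array of
#' nonnegative integers bounded by the sensor ceiling `dn_max`.  The default
#' ceiling is 65,552 DN, the maximum digital number of the camera this
#' package models (note: deliberately not 2^16 - 1; it is configurable).
#'
#' @param data numeric array, height x width x n_bands; integral values in
#'   `[0, dn_max]`.
#' @param wavelengths wavelength axis, length `dim(data)[3]`.
#' @param dn_max DN ceiling (default 65552).
#' @return object of class `hyperspec_cube`.
#' @export
hyperspec_cube <- function(data, wavelengths, dn_max = 65552) {
  if (length(dim(data)) != 3L)
    abort("cube data must be a 3-d array (height x width x bands)")
  check_axis(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    abort("cube has %d bands but axis has %d wavelengths",
          dim(data)[3], length(wavelengths))
  if (min(data) < 0 || max(data) > dn_max)
    abort("DN values must lie in [0, %s]", format(dn_max))
  storage.mode(data) <- "double"
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 dn_max = dn_max), class = "hyperspec_cube")
}

#' @export
print.hyperspec_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral cube: %d x %d pixels, %d bands (%.1f-%.1f nm), dn_max %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              format(x$dn_max)))
  invisible(x)
}

#' Black/white reflectance correction
#'
#' Converts a raw DN cube to reflectance using the dark-current reference
#' `B` and standard-whiteboard reference `W`:
#' \deqn{R = dn_{max} \times (R_0 - B) / (W - B)}
#' applied per pixel per band.  Pixels where `W = B` in any band are masked
#' invalid (their values are set to `NA`).  Corrected values outside
#' `[0, dn_max]` (e.g. specular highlights) are retained, not clipped --
#' clipping would bias downstream ROI means -- but their count is recorded.
#'
#' @param raw,white,black [hyperspec_cube()] objects of identical shape and
#'   axis.
#' @return object of class `reflectance_image`: list with `values`
#'   (height x width x bands, reflectance on the DN scale), `valid`
#'   (height x width logical mask), `wavelengths`, `dn_max`,
#'   `n_out_of_range`.
#' @examples
#' wl <- spectral_axis(3)
#' w <- hyperspec_cube(array(1000, c(2, 2, 3)), wl)
#' b <- hyperspec_cube(array(200, c(2, 2, 3)), wl)
#' r0 <- hyperspec_cube(array(600, c(2, 2, 3)), wl)
#' correct_reflectance(r0, w, b)$values[1, 1, 1]   # 32776
#' @export
correct_reflectance <- function(raw, white, black) {
  for (x in list(raw, white, black))
    stopifnot(inherits(x, "hyperspec_cube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(black$data)))
    abort("raw, white and black cubes must share one shape")
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, black$wavelengths)))
    abort("raw, white and black cubes must share one wavelength axis")
  denom <- white$data - black$data
  vals <- raw$dn_max * (raw$data - black$data) / denom
  bad <- denom == 0
  valid <- !apply(bad, c(1, 2), any)
  if (!any(valid)) abort("all pixels invalid: W = B everywhere in some band")
  vals[bad] <- NA_real_
  # invalidate the whole spectrum of a pixel that is bad in any band
  vals[array(rep(!valid, times = dim(vals)[3]), dim(vals))] <- NA_real_
  n_oor <- sum(vals < 0 | vals > raw$dn_max, na.rm = TRUE)
  structure(list(values = vals, valid = valid,
                 wavelengths = raw$wavelengths, dn_max = raw$dn_max,
                 n_out_of_range = n_oor),
            class = "reflectance_image")
}

#' @export
print.reflectance_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Reflectance image: %d x %d pixels, %d bands; %d valid pixels, %d values out of [0, dn_max]\n",
              d[1], d[2], d[3], sum(x$valid), x$n_out_of_range))
  invisible(x)
}

#' ROI mean spectrum
#'
#' Per-band arithmetic mean of the reflectance over the pixels of a region
#' of interest (ROI), the standard way one sample's spectrum is read off a
#' corrected hyperspectral image.
#'
#' @param image a [reflectance_image][correct_reflectance].
#' @param mask logical height x width matrix; `TRUE` marks in-ROI pixels.
#'   Defaults to every valid pixel.
#' @return numeric vector of length n_bands.
#' @export
extract_roi_mean <- function(image, mask = NULL) {
  stopifnot(inherits(image, "reflectance_image"))
  d <- dim(image$values)
  if (is.null(mask)) mask <- image$valid
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    abort("mask must be a logical height x width matrix")
  eff <- mask & image$valid
  if (!any(eff)) abort("ROI mask selects no valid pixels")
  flat <- matrix(image$values, d[1] * d[2], d[3])
  colMeans(flat[as.vector(eff), , drop = FALSE])
}

#' Threshold-based ROI helper
#'
#' Marks as in-ROI every valid pixel whose mean reflectance over bands
#' exceeds `threshold` (on the DN scale) -- a stand-in for interactive ROI
#' drawing when the sample fills the bright part of the scene.
#'
#' @param image a `reflectance_image`.
#' @param threshold reflectance threshold on the DN scale.
#' @return logical height x width mask.
#' @export
roi_threshold <- function(image, threshold) {
  stopifnot(inherits(image, "reflectance_image"))
  m <- apply(image$values, c(1, 2), mean)
  mask <- !is.na(m) & m > threshold & image$valid
  if (!any(mask)) abort("threshold ROI selects no pixels")
  mask
}

#' Synthesize a DN cube (inverse of the black/white correction)
#'
#' Builds a raw DN cube plus matching white and black reference cubes such
#' that applying [correct_reflectance()] recovers the input spectrum up to
#' quantization (at most 0.5 DN per pixel before ROI averaging).  Every
#' pixel carries the same spectrum, optionally with integer DN jitter.
#' Defaults (`black_level = 0`, `white_level = dn_max`) are the only
#' references that keep raw DN within `[0, dn_max]` while preserving the
#' 0.5 DN quantization bound.
#'
#' @param spectrum reflectance spectrum on the DN scale, values in
#'   `[0, dn_max]` (multiply unit reflectance by `dn_max`).
#' @param shape height x width of the synthesized scene.
#' @param wavelengths wavelength axis (default built to match `spectrum`).
#' @param dn_max DN ceiling.
#' @param black_level,white_level reference DN levels (scalar or per band);
#'   must satisfy `white > black` everywhere.
#' @param jitter_sd SD of optional per-pixel DN jitter (default 0).
#' @param seed seed used when `jitter_sd > 0`.
#' @return list with elements `raw`, `white`, `black`, all
#'   [hyperspec_cube()] objects.
#' @export
synthesize_cube <- function(spectrum, shape = c(8L, 8L),
                            wavelengths = spectral_axis(length(spectrum)),
                            dn_max = 65552, black_level = 0,
                            white_level = dn_max, jitter_sd = 0, seed = 1L) {
  if (any(spectrum < 0) || any(spectrum > dn_max))
    abort("spectrum must lie in [0, dn_max]")
  if (any(shape < 1)) abort("shape must be positive")
  nb <- length(spectrum)
  check_axis(wavelengths)
  if (length(wavelengths) != nb) abort("axis length must match spectrum")
  B <- rep_len(black_level, nb)
  W <- rep_len(white_level, nb)
  if (any(W - B <= 0)) abort("white minus black must be positive in every band")
  h <- shape[1]; w <- shape[2]
  r0_band <- B + spectrum / dn_max * (W - B)
  raw <- aperm(array(rep(r0_band, each = h * w), c(h, w, nb)), c(1, 2, 3))
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    raw <- raw + rnorm(length(raw), 0, jitter_sd)
  }
  raw <- round(pmin(pmax(raw, 0), dn_max))
  mk <- function(level) hyperspec_cube(
    aperm(array(rep(rep_len(level, nb), each = h * w), c(h, w, nb)), c(1, 2, 3)),
    wavelengths, dn_max)
  list(raw = hyperspec_cube(raw, wavelengths, dn_max),
       white = mk(W), black = mk(B))
}
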
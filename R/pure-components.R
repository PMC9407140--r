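#' Pure-component spectral library
#'
#' Evaluates nonnegative absorptivity profiles on a wavelength axis.  Each
#' component is described as a sum of Gaussian peaks; the profile value at
#' wavelength \eqn{\lambda} is \eqn{\sum_j h_j \exp(-(\lambda-c_j)^2/(2 w_j^2))},
#' in absorbance units per unit concentration (dry-mass %).  These synthetic
#' signatures stand in for the (unpublished) absorptivity spectra of real tea
#' constituents; the forward model that uses them is plain Beer--Lambert
#' mixing, which is what the downstream calibration pipeline inverts.
#'
#' @param wavelengths wavelength axis in nm (see [spectral_axis()]).
#' @param peaks named list, one element per component; each element is a
#'   data.frame with columns `center` (nm, inside the axis range), `width`
#'   (nm, > 0) and `height` (AU per unit concentration, >= 0).
#' @return an object of class `pure_component_library`: list with `profiles`
#'   (n_bands x n_components matrix, components in columns), `wavelengths`,
#'   and `peaks` (the input parameterization).
#' @examples
#' wl <- spectral_axis(60)
#' lib <- make_pure_spectra(wl, list(
#'   TPs = data.frame(center = 700, width = 30, height = 1)))
#' which.max(lib$profiles[, "TPs"]) == which.min(abs(wl - 700))
#' @export
make_pure_spectra <- function(wavelengths, peaks) {
  check_axis(wavelengths)
  if (!is.list(peaks) || is.null(names(peaks)) || any(!nzchar(names(peaks))))
    abort("'peaks' must be a named list of per-component peak tables")
  profiles <- vapply(names(peaks), function(nm) {
    pk <- peaks[[nm]]
    if (is.null(pk) || NROW(pk) == 0L)
      abort("component '%s' has no peaks: it would be spectrally invisible", nm)
    pk <- as.data.frame(pk)
    if (!all(c("center", "width", "height") %in% names(pk)))
      abort("peak table for '%s' needs columns center, width, height", nm)
    if (any(pk$center < min(wavelengths)) || any(pk$center > max(wavelengths)))
      abort("component '%s': peak center outside the wavelength axis", nm)
    if (any(pk$width <= 0)) abort("component '%s': peak widths must be > 0", nm)
    if (any(pk$height < 0)) abort("component '%s': peak heights must be >= 0", nm)
    prof <- numeric(length(wavelengths))
    for (j in seq_len(nrow(pk)))
      prof <- prof + pk$height[j] *
        exp(-(wavelengths - pk$center[j])^2 / (2 * pk$width[j]^2))
    prof
  }, numeric(length(wavelengths)))
  structure(list(profiles = profiles, wavelengths = wavelengths, peaks = peaks),
            class = "pure_component_library")
}

#' Default pure-component library for the tea scenario
#'
#' Gaussian signatures for the three target analytes (TPs, FAA, CAF) plus two
#' interfering components: `pigment`, a varying absorber that makes band
#' selection non-trivial, and `matrix`, the broad near-constant dry-leaf
#' background that dominates total absorbance (so that per-sample scatter
#' correction mainly sees scatter, not chemistry).  The analyte profiles are
#' placed so the 3-column profile matrix is far from collinear (finite,
#' modest condition number).  Peak placements are a package design choice:
#' no physical band assignment is implied.
#'
#' @param wavelengths wavelength axis in nm.
#' @return a `pure_component_library` with components TPs, FAA, CAF, pigment.
#' @export
default_component_library <- function(wavelengths = spectral_axis()) {
  make_pure_spectra(wavelengths, list(
    TPs = data.frame(center = c(540, 705, 980),
                     width  = c(40, 28, 35),
                     height = c(0.030, 0.022, 0.012)),
    FAA = data.frame(center = c(452, 640, 760, 920),
                     width  = c(16, 25, 28, 35),
                     height = c(0.070, 0.038, 0.050, 0.030)),
    CAF = data.frame(center = c(405, 600, 860),
                     width  = c(12, 20, 22),
                     height = c(0.080, 0.040, 0.035)),
    pigment = data.frame(center = c(520, 970),
                         width  = c(80, 60),
                         height = c(0.15, 0.25)),
    matrix = data.frame(center = c(560, 900),
                        width  = c(220, 180),
                        height = c(0.88, 0.80))
  ))
}

#' @export
print.pure_component_library <- function(x, ...) {
  cat("Pure-component library:", ncol(x$profiles), "components on",
      length(x$wavelengths), "bands\n")
  cat("  components:", paste(colnames(x$profiles), collapse = ", "), "\n")
  invisible(x)
}
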
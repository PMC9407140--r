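#' Standard curve for a colorimetric assay
#'
#' A linear calibration `A = slope * C + intercept` relating absorbance to
#' analyte concentration, with its goodness of fit.  [fit_standard_curve()]
#' estimates one by ordinary least squares from calibration points;
#' `standard_curve()` constructs one from known coefficients (e.g. a curve
#' reported by the instrument lab, such as A = 34.625 C - 0.0895 for the
#' ninhydrin free-amino-acid assay).
#'
#' @param slope,intercept line coefficients (absorbance per concentration
#'   unit; slope must be nonzero so the curve can be inverted).
#' @param r_squared squared Pearson correlation of the fit, in [0, 1].
#' @param analyte analyte tag (e.g. "FAA", "CAF").
#' @return object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_,
                           analyte = NA_character_) {
  if (!is.finite(slope) || slope == 0)
    abort("standard curve slope must be nonzero finite")
  if (is.finite(r_squared) && (r_squared < 0 || r_squared > 1))
    abort("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, analyte = analyte),
            class = "standard_curve")
}

#' @rdname standard_curve
#' @param concentrations,absorbances calibration points (>= 3; the
#'   concentrations must not all be equal).
#' @export
fit_standard_curve <- function(concentrations, absorbances,
                               analyte = NA_character_) {
  if (length(concentrations) != length(absorbances))
    abort("concentrations and absorbances must have equal length")
  if (length(concentrations) < 3)
    abort("a standard curve needs at least 3 calibration points")
  if (sd(concentrations) == 0)
    abort("degenerate calibration: concentrations all equal")
  fit <- lm(absorbances ~ concentrations)
  b <- unname(coef(fit))
  r2 <- cor(concentrations, absorbances)^2
  standard_curve(slope = b[2], intercept = b[1], r_squared = r2,
                 analyte = analyte)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve [%s]: A = %.6g C %+.6g  (R^2 = %.4f)\n",
              x$analyte, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
format.standard_curve <- function(x, ...) {
  sprintf("A = %.6g C %+.6g", x$slope, x$intercept)
}

#' Invert a standard curve
#'
#' Converts a measured absorbance to concentration, `C = (A - intercept) /
#' slope`.
#'
#' @param curve a [standard_curve()].
#' @param absorbance measured absorbance (vectorized).
#' @return concentration(s) in the curve's units.
#' @export
invert_standard_curve <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Reference standard curves used in the worked examples
#'
#' The calibration lines used throughout the package's examples for the
#' ninhydrin (FAA) and caffeine (CAF) assays.
#'
#' @return named list of two [standard_curve()] objects, `FAA` and `CAF`.
#' @export
default_standard_curves <- function() {
  list(FAA = standard_curve(34.625, -0.0895, 0.9983, "FAA"),
       CAF = standard_curve(26.411, 0.0141, 0.9903, "CAF"))
}

# shared input checks for the content formulas
check_assay_denominators <- function(V1, V2, m, omega, need_V2 = TRUE) {
  if (any(m <= 0)) abort("sample mass m must be positive")
  if (any(omega <= 0) || any(omega > 1))
    abort("dry-matter fraction omega must lie in (0, 1]")
  if (any(V1 <= 0)) abort("total test-solution volume V1 must be positive")
  if (need_V2) {
    if (any(V2 <= 0)) abort("aliquot volume V2 must be positive")
    if (any(V2 > V1)) abort("aliquot volume V2 cannot exceed V1")
  }
  invisible(TRUE)
}

#' Tea polyphenols content (dry-mass %)
#'
#' Ferrous-tartrate colorimetric determination:
#' \deqn{TPs = A_1 \times 1.957 \times 2 / 1000 \times (V_1/V_2) / (m \omega) \times 100}
#' where `A1` is the absorbance at 540 nm, `V1` the total test-solution
#' volume (mL), `V2` the aliquot used (mL), `m` the sample mass (g) and
#' `omega` the dry-matter fraction (0--1].  The constant 1.957 x 2 embeds
#' the assay calibration and dilution factors and is implemented verbatim.
#'
#' @param A1 absorbance at 540 nm (>= 0).
#' @param V1,V2 volumes in mL.
#' @param m sample mass in g.
#' @param omega dry-matter fraction in (0, 1].
#' @return TPs content as dry-mass fraction in percent.
#' @examples
#' tps_content(0.5, 500, 1, 1.5, 1)   # 65.233...
#' @export
tps_content <- function(A1, V1, V2, m, omega) {
  if (any(A1 < 0)) abort("absorbance A1 must be >= 0")
  check_assay_denominators(V1, V2, m, omega)
  A1 * 1.957 * 2 / 1000 * (V1 / V2) / (m * omega) * 100
}

#' Free amino acids content (dry-mass %)
#'
#' Ninhydrin colorimetric determination:
#' \deqn{FAA = C_1 / 1000 \times (V_1/V_2) / (m \omega) \times 100}
#' where `C1` is the theanine mass (mg) found from the absorbance `A2` via
#' the FAA standard curve.
#'
#' @param C1 theanine mass in the measured aliquot (mg, >= 0).
#' @inheritParams tps_content
#' @return FAA content as dry-mass fraction in percent.
#' @examples
#' faa_content(1.425, 500, 1, 1.5, 0.95)  # 50
#' @export
faa_content <- function(C1, V1, V2, m, omega) {
  if (any(C1 < 0)) abort("curve-derived mass C1 must be >= 0")
  check_assay_denominators(V1, V2, m, omega)
  C1 / 1000 * (V1 / V2) / (m * omega) * 100
}

#' Caffeine content (dry-mass %)
#'
#' UV spectrophotometric determination at 274 nm:
#' \deqn{CAF = C_2 \times V_1 / 1000 \times (100/10) \times (50/25) / (m \omega) \times 100}
#' where `C2` (mg/mL) is read from the caffeine standard curve and the
#' printed dilution factors 100/10 and 50/25 reflect the two-stage dilution
#' of the test solution.
#'
#' @param C2 curve-derived concentration in mg/mL (>= 0).
#' @inheritParams tps_content
#' @return CAF content as dry-mass fraction in percent.
#' @examples
#' caf_content(0.001, 500, 1.5, 1)  # 0.6667
#' @export
caf_content <- function(C2, V1, m, omega) {
  if (any(C2 < 0)) abort("curve-derived concentration C2 must be >= 0")
  check_assay_denominators(V1, V2 = NULL, m, omega, need_V2 = FALSE)
  C2 * V1 / 1000 * (100 / 10) * (50 / 25) / (m * omega) * 100
}

#' Compute a chemistry table from raw assay measurements
#'
#' Takes a table of raw assay inputs (one row per sample: absorbances
#' `A1`, `A2`, `A3`, volumes `V1`, `V2`, mass `m`, dry-matter fraction
#' `omega`) and the FAA/CAF standard curves, and returns the TPs/FAA/CAF
#' dry-mass percentages.
#'
#' @param assay data.frame with columns `sample_id`, `A1`, `A2`, `A3`,
#'   `V1`, `V2`, `m`, `omega`.
#' @param curves named list with `FAA` and `CAF` [standard_curve()]s
#'   (default [default_standard_curves()]).
#' @return data.frame with `sample_id`, `TPs`, `FAA`, `CAF`.
#' @export
assay_chemistry <- function(assay, curves = default_standard_curves()) {
  need <- c("sample_id", "A1", "A2", "A3", "V1", "V2", "m", "omega")
  if (!all(need %in% names(assay)))
    abort("assay table must have columns: %s", paste(need, collapse = ", "))
  C1 <- invert_standard_curve(curves$FAA, assay$A2)
  C2 <- invert_standard_curve(curves$CAF, assay$A3)
  data.frame(
    sample_id = assay$sample_id,
    TPs = tps_content(assay$A1, assay$V1, assay$V2, assay$m, assay$omega),
    FAA = faa_content(C1, assay$V1, assay$V2, assay$m, assay$omega),
    CAF = caf_content(C2, assay$V1, assay$m, assay$omega),
    stringsAsFactors = FALSE)
}
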
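#' Configuration for the characteristic-band selectors
#'
#' All algorithmic constants of the three selectors, each exposed because
#' the underlying methods are used here in their original formulations:
#'
#' * SPA: candidate subset sizes `spa_size` (default 5--30).
#' * CARS: `cars_runs` Monte Carlo runs (default 50), per-run sampling
#'   fraction `cars_fraction` (default 0.8), and whether the adaptive
#'   reweighted sampling stage is applied (`cars_ars`, default `TRUE`;
#'   with it off a run is deterministic given the sample-subset seed).
#' * UVE: number of appended noise variables `uve_noise` (default: as many
#'   as real bands), their amplitude scale `uve_amplitude` (default 1e-10),
#'   the stability cutoff percentile over the noise variables
#'   `uve_percentile` (default 99), the CV scheme `uve_cv`
#'   (`"loo"`, the default, or `"kfold"`), and an optional fixed
#'   latent-component count `uve_ncomp` (default `NULL`: chosen by inner
#'   CV; fix it when the latent dimension is known).
#' * Shared: `cv_folds` for RMSECV evaluation (default 5) and `ncomp_max`,
#'   the ceiling on PLS latent components chosen by inner CV (default 10).
#'
#' @param spa_size length-2 integer range of SPA subset sizes.
#' @param cars_runs,cars_fraction,cars_ars CARS settings.
#' @param uve_noise,uve_amplitude,uve_percentile,uve_cv UVE settings.
#' @param cv_folds,ncomp_max shared model-evaluation settings.
#' @return list of class `selector_config`.
#' @export
selector_config <- function(spa_size = c(5L, 30L),
                            cars_runs = 50L, cars_fraction = 0.8,
                            cars_ars = TRUE,
                            uve_noise = NULL, uve_amplitude = 1e-10,
                            uve_percentile = 99, uve_cv = c("loo", "kfold"),
                            uve_ncomp = NULL,
                            cv_folds = 5L, ncomp_max = 10L) {
  uve_cv <- match.arg(uve_cv)
  stopifnot(length(spa_size) == 2, spa_size[1] >= 1, spa_size[2] >= spa_size[1],
            cars_runs >= 2, cars_fraction > 0, cars_fraction < 1,
            uve_amplitude > 0, uve_percentile > 50, uve_percentile <= 100,
            cv_folds >= 2, ncomp_max >= 1)
  structure(list(spa_size = as.integer(spa_size),
                 cars_runs = as.integer(cars_runs),
                 cars_fraction = cars_fraction, cars_ars = isTRUE(cars_ars),
                 uve_noise = uve_noise, uve_amplitude = uve_amplitude,
                 uve_percentile = uve_percentile, uve_cv = uve_cv,
                 uve_ncomp = uve_ncomp,
                 cv_folds = as.integer(cv_folds),
                 ncomp_max = as.integer(ncomp_max)),
            class = "selector_config")
}

#' Band selection result
#'
#' @param method selector tag ("spa", "cars", "uve", or "none").
#' @param indices retained band indices into the current axis (unique,
#'   ascending, >= 1 of them).
#' @param wavelengths full wavelength axis the indices refer to.
#' @param diagnostics selector-specific diagnostics (RMSECV trace, stability
#'   values, per-start scores, ...).
#' @return object of class `band_selection`.
#' @export
band_selection <- function(method, indices, wavelengths, diagnostics = list()) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices)) abort("band selection must retain at least one band")
  if (min(indices) < 1L || max(indices) > length(wavelengths))
    abort("band indices outside the axis")
  structure(list(method = method, indices = indices,
                 wavelengths = wavelengths[indices],
                 n_bands = length(indices), axis = wavelengths,
                 diagnostics = diagnostics),
            class = "band_selection")
}

#' Format selected bands as wavelength ranges
#'
#' Collapses runs of index-adjacent selected bands into "start--end" labels
#' in nm (e.g. `"519-522"`), the conventional way characteristic-band sets
#' are tabulated.
#'
#' @param sel a [band_selection()] object.
#' @return character vector of range labels.
#' @export
format_band_ranges <- function(sel) {
  stopifnot(inherits(sel, "band_selection"))
  idx <- sel$indices
  wl <- round(sel$axis)
  runs <- cumsum(c(1L, diff(idx) != 1L))
  vapply(split(idx, runs), function(g) {
    if (length(g) == 1L) sprintf("%d", wl[g]) else
      sprintf("%d-%d", wl[g[1]], wl[g[length(g)]])
  }, "", USE.NAMES = FALSE)
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("Band selection [%s]: %d of %d bands retained\n",
              toupper(x$method), x$n_bands, length(x$axis)))
  cat("  bands (nm):", paste(format_band_ranges(x), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a band selection to JSON
#'
#' @param sel a [band_selection()].
#' @param path output path.
#' @export
write_band_selection <- function(sel, path) {
  stopifnot(inherits(sel, "band_selection"))
  jsonlite::write_json(
    list(method = sel$method, n_bands = sel$n_bands,
         indices = sel$indices, wavelengths = sel$wavelengths,
         ranges = format_band_ranges(sel), diagnostics = sel$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# internal: seeded fold assignment shared by the selectors
make_folds <- function(n, folds, seed) {
  set.seed(as.integer(seed))
  sample(rep(seq_len(folds), length.out = n))
}
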
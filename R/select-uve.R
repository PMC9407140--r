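#' Uninformative variable elimination (UVE)
#'
#' Thresholds PLS regression-coefficient stability against artificial noise
#' variables.  Uniform random columns scaled to `uve_amplitude` are appended
#' to X (by default as many as there are real bands); the configured CV
#' scheme (leave-one-out by default) refits PLS in every fold; the stability
#' of column j is \eqn{c_j = \mathrm{mean}(b_j)/\mathrm{sd}(b_j)} over the
#' folds.  The cutoff is the `uve_percentile` percentile of |c| over the
#' noise columns; real bands with |c| above the cutoff are retained.  The
#' appended noise columns are internal and never part of the result.
#'
#' The latent-component count is `uve_ncomp` when configured, otherwise it
#' is chosen once on the full augmented matrix by K-fold CV (up to
#' `ncomp_max`), and is reused in every fold.  A column
#' whose coefficient has zero spread gets infinite stability of the sign of
#' its mean (retained iff its mean is nonzero); this is reported in the
#' diagnostics.  If no real band clears the cutoff, the single most stable
#' band is retained with a warning.
#'
#' @param X predictor matrix (n >= 3).
#' @param y response vector.
#' @param config a [selector_config()]; uses the `uve_*` fields,
#'   `cv_folds` and `ncomp_max`.
#' @param seed RNG seed for the noise columns (and fold assignment when
#'   `uve_cv = "kfold"`).
#' @param wavelengths optional axis for reporting (defaults to band index).
#' @return a [band_selection()]; diagnostics carry the per-column stability
#'   values, the cutoff, and the noise-column stabilities.
#' @export
uve <- function(X, y, config = selector_config(), seed = 1L,
                wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) abort("UVE needs at least 3 samples")
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  k_noise <- as.integer(config$uve_noise %||% p)
  set.seed(as.integer(seed))
  noise <- matrix(runif(n * k_noise, -1, 1) * config$uve_amplitude, n, k_noise)
  Z <- cbind(X, noise)
  ncomp_cap <- max(1L, min(config$ncomp_max, ncol(Z), n - 3L))
  ncomp <- config$uve_ncomp
  if (is.null(ncomp)) {
    cv <- pls_cv(Z, y, ncomp_max = ncomp_cap, folds = config$cv_folds,
                 seed = sample.int(.Machine$integer.max, 1L))
    ncomp <- cv$best
  } else ncomp <- min(as.integer(ncomp), ncomp_cap)
  folds <- if (config$uve_cv == "loo") n else config$cv_folds
  assign <- if (config$uve_cv == "loo") seq_len(n)
            else make_folds(n, folds, sample.int(.Machine$integer.max, 1L))
  B <- matrix(NA_real_, folds, ncol(Z))
  for (k in seq_len(folds)) {
    tr <- assign != k
    fit <- pls_fit(Z[tr, , drop = FALSE], y[tr],
                   ncomp = min(ncomp, sum(tr) - 1L))
    B[k, ] <- coef(fit)
  }
  mu <- colMeans(B)
  sdv <- apply(B, 2L, sd)
  stab <- mu / sdv
  zero_sd <- sdv == 0
  if (any(zero_sd)) {
    stab[zero_sd] <- ifelse(mu[zero_sd] == 0, 0, sign(mu[zero_sd]) * Inf)
    message(sprintf("uve: %d column(s) with zero coefficient spread", sum(zero_sd)))
  }
  cutoff <- quantile(abs(stab[(p + 1L):(p + k_noise)]),
                     config$uve_percentile / 100, names = FALSE)
  keep <- which(abs(stab[seq_len(p)]) > cutoff)
  if (!length(keep)) {
    warning("UVE: no band exceeded the noise cutoff; retaining the most stable band")
    keep <- which.max(abs(stab[seq_len(p)]))
  }
  band_selection("uve", keep, wavelengths,
                 diagnostics = list(stability = stab[seq_len(p)],
                                    noise_stability = stab[(p + 1L):(p + k_noise)],
                                    cutoff = cutoff, ncomp = ncomp))
}
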
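#' Exponentially decreasing retention schedule for CARS
#'
#' Closed form of the fraction of bands kept at each Monte Carlo run:
#' \eqn{r_i = a e^{-k i}} with \eqn{a = (p/2)^{1/(N-1)}} and
#' \eqn{k = \log(p/2)/(N-1)}, calibrated so run 1 keeps all p bands and run
#' N keeps exactly 2.  The retained count at run i is \eqn{\lceil p r_i \rceil}.
#'
#' @param p number of bands.
#' @param N number of Monte Carlo runs.
#' @return integer vector of length N: retained band counts per run
#'   (monotone nonincreasing from p to 2).
#' @examples
#' s <- cars_schedule(360, 50)
#' s[1]; s[50]    # 360, 2
#' @export
cars_schedule <- function(p, N) {
  stopifnot(p >= 2, N >= 2)
  i <- seq_len(N)
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  # guard the ceiling against floating-point fuzz at the exact endpoints
  pmin(as.integer(ceiling(p * a * exp(-k * i) - 1e-9)), p)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte Carlo wavelength selection driven by the magnitude of PLS
#' regression coefficients.  In run i (of N):
#'
#' 1. fit PLS on a random `cars_fraction` subset of the samples, restricted
#'    to the currently retained bands, with the latent-component count
#'    chosen by inner cross-validation up to `ncomp_max`;
#' 2. rank the retained bands by absolute regression coefficient and apply
#'    enforced elimination: keep the top \eqn{\lceil p r_i \rceil} bands of
#'    the exponentially decreasing schedule ([cars_schedule()]);
#' 3. (default) adaptive reweighted sampling: draw that many bands from the
#'    survivors with probability proportional to |coefficient|, with
#'    replacement, keeping the unique draws;
#' 4. record the K-fold RMSECV of a PLS model on the survivor set over all
#'    samples.
#'
#' The survivor set of the run with minimal RMSECV is returned (ties go to
#' the run with fewer bands).  If a survivor set collapses below 2 bands
#' the loop stops early and what exists is evaluated.
#'
#' @param X predictor matrix (n x p, p >= 2).
#' @param y response vector.
#' @param config a [selector_config()]; uses `cars_runs`, `cars_fraction`,
#'   `cars_ars`, `cv_folds`, `ncomp_max`.
#' @param seed RNG seed; the whole trajectory is reproducible.
#' @param wavelengths optional axis for reporting (defaults to band index).
#' @return a [band_selection()]; diagnostics carry the per-run RMSECV
#'   trace, retained counts and the winning run index.
#' @export
cars <- function(X, y, config = selector_config(), seed = 1L,
                 wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) abort("CARS needs at least 2 bands")
  if (n < config$cv_folds) abort("CARS needs n >= cv_folds")
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  N <- config$cars_runs
  keep_n <- cars_schedule(p, N)
  n_sub <- max(2L, round(config$cars_fraction * n))
  set.seed(as.integer(seed))
  retained <- seq_len(p)
  sets <- vector("list", N)
  rmsecv <- rep(NA_real_, N)
  n_retained <- rep(NA_integer_, N)
  ncomp_used <- rep(NA_integer_, N)
  for (i in seq_len(N)) {
    sub <- sample.int(n, n_sub)
    Xs <- X[sub, retained, drop = FALSE]
    ncomp_cap <- max(1L, min(config$ncomp_max, length(retained), n_sub - 2L))
    cv_sub <- pls_cv(Xs, y[sub], ncomp_max = ncomp_cap,
                     folds = min(config$cv_folds, n_sub),
                     seed = sample.int(.Machine$integer.max, 1L))
    fit <- pls_fit(Xs, y[sub], ncomp = cv_sub$best)
    w <- abs(coef(fit))
    # enforced elimination by the decreasing schedule
    k_i <- min(keep_n[i], length(retained))
    top <- retained[order(w, decreasing = TRUE)[seq_len(k_i)]]
    if (config$cars_ars && length(top) > 1L) {
      # p weighted draws with replacement (the method's original count);
      # the unique survivors then track the enforced-elimination schedule
      prob <- w[match(top, retained)]
      if (sum(prob) <= 0) prob <- rep(1, length(top))
      surv <- unique(sample(top, size = p, replace = TRUE, prob = prob))
    } else surv <- top
    retained <- sort(surv)
    n_retained[i] <- length(retained)
    if (length(retained) < 2L) {
      # collapsed: evaluate what exists and stop
      cv_all <- pls_cv(X[, retained, drop = FALSE], y, ncomp_max = 1L,
                       folds = config$cv_folds,
                       seed = sample.int(.Machine$integer.max, 1L))
      sets[[i]] <- retained
      rmsecv[i] <- min(cv_all$rmsecv)
      ncomp_used[i] <- cv_all$best
      break
    }
    ncomp_cap <- max(1L, min(config$ncomp_max, length(retained)))
    cv_all <- pls_cv(X[, retained, drop = FALSE], y, ncomp_max = ncomp_cap,
                     folds = config$cv_folds,
                     seed = sample.int(.Machine$integer.max, 1L))
    sets[[i]] <- retained
    rmsecv[i] <- min(cv_all$rmsecv)
    ncomp_used[i] <- cv_all$best
  }
  done <- which(is.finite(rmsecv))
  # minimal RMSECV; ties -> fewer bands
  ord <- done[order(rmsecv[done], n_retained[done])]
  best <- ord[1L]
  band_selection("cars", sets[[best]], wavelengths,
                 diagnostics = list(rmsecv_trace = rmsecv,
                                    n_retained = n_retained,
                                    schedule = keep_n,
                                    ncomp = ncomp_used,
                                    best_run = best))
}
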
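#' Random 4:1 train/test split
#'
#' Uniform random split without replacement: the test set gets
#' `round(n / (ratio + 1))` samples, the remainder trains.  The default
#' ratio 4 reproduces the conventional 4:1 calibration/prediction split
#' (116 samples -> 93 train / 23 test).
#'
#' @param sample_ids character or integer vector of sample identifiers
#'   (n >= 5).
#' @param ratio train:test ratio (default 4).
#' @param seed RNG seed; same seed, same split.
#' @return object of class `split_spec`: list with `train`, `test`,
#'   `ratio`, `seed`.
#' @examples
#' s <- split_train_test(sprintf("S%03d", 1:116), seed = 1)
#' length(s$train); length(s$test)   # 93, 23
#' @export
split_train_test <- function(sample_ids, ratio = 4, seed = 1L) {
  n <- length(sample_ids)
  if (n < 5L) abort("need at least 5 samples to split, got %d", n)
  if (anyDuplicated(sample_ids)) abort("sample ids must be unique")
  n_test <- round(n / (ratio + 1))
  n_test <- max(1L, min(n - 1L, n_test))
  set.seed(as.integer(seed))
  test_idx <- sort(sample.int(n, n_test))
  structure(list(train = sample_ids[-test_idx], test = sample_ids[test_idx],
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Train/test split %g:1 (seed %d): %d train / %d test\n",
              x$ratio, x$seed, length(x$train), length(x$test)))
  invisible(x)
}

#' Calibration/prediction evaluation metrics
#'
#' The standard chemometric report card for one fitted model:
#' RC^2 and RMSEC on the calibration (training) set, RP^2 and RMSEP on the
#' prediction (test) set, the supplied cross-validation RMSECV, and the
#' relative predictive deviation \deqn{RPD = sd(y_{test}) / RMSEP} (sd with
#' the n-1 denominator).  R^2 is defined as 1 - SSE/SST.  A model with
#' RPD < 1.4 is flagged `"poor"`; an undefined RPD (zero RMSEP or
#' zero-variance test response) is flagged rather than reported as
#' infinite.
#'
#' @param model a fitted model with a `predict(model, X)` method.
#' @param X_train,y_train calibration data.
#' @param X_test,y_test prediction data (disjoint from calibration).
#' @param rmsecv cross-validated RMSE (optional, `NA` if not computed).
#' @param n_bands number of bands the model uses (for reporting).
#' @return one-row data.frame: `rc2`, `rmsec`, `rmsecv`, `rp2`, `rmsep`,
#'   `rpd`, `n_bands`, `flag` ("ok", "poor", or "rpd-undefined").
#' @export
evaluate_model <- function(model, X_train, y_train, X_test, y_test,
                           rmsecv = NA_real_, n_bands = ncol(X_train)) {
  pred_tr <- predict(model, X_train)
  pred_te <- predict(model, X_test)
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
  rmsec <- rmse(y_train, pred_tr)
  rmsep <- rmse(y_test, pred_te)
  sd_test <- sd(y_test)
  if (sd_test == 0 || rmsep == 0) {
    rpd <- NA_real_
    flag <- "rpd-undefined"
  } else {
    rpd <- sd_test / rmsep
    flag <- if (rpd < 1.4) "poor" else "ok"
  }
  data.frame(rc2 = r2(y_train, pred_tr), rmsec = rmsec, rmsecv = rmsecv,
             rp2 = if (sd_test > 0) r2(y_test, pred_te) else NA_real_,
             rmsep = rmsep, rpd = rpd, n_bands = n_bands, flag = flag,
             stringsAsFactors = FALSE)
}
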
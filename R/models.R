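#' Fit a regression model (PLS, SVM or random forest)
#'
#' One contract for the three model families used in the calibration grid.
#' PLS is the in-package [pls_fit()] (latent components via `hyperparams$ncomp`,
#' or chosen by CV when omitted); support vector regression wraps
#' [e1071::svm()] (eps-regression, radial kernel by default); random forest
#' wraps [randomForest::randomForest()] and is reproducible under `seed`.
#'
#' @param family `"pls"`, `"svm"` (alias `"svr"`), or `"rf"`.
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param hyperparams named list.  PLS: `ncomp`, `ncomp_max`, `folds`.
#'   SVM: `kernel` (default "radial"), `cost` (default 10), `epsilon`
#'   (default 0.01), `gamma` (default 1/p).  RF: `ntree` (default 500),
#'   `mtry` (default p/3), `nodesize`.
#' @param seed RNG seed (matters for RF and for PLS component CV).
#' @return object of class `tea_regressor` with a [predict][predict.tea_regressor]
#'   method that accepts only matrices with the training band count.
#' @export
fit_regressor <- function(family, X, y, hyperparams = list(), seed = 1L) {
  if (identical(family, "svr")) family <- "svm"
  if (!family %in% c("pls", "svm", "rf"))
    abort("unknown model family '%s' (use pls, svm/svr, or rf)", family)
  X <- as.matrix(X); y <- as.numeric(y)
  hp <- hyperparams
  fit <- switch(family,
    pls = {
      ncomp <- hp$ncomp
      if (is.null(ncomp)) {
        cv <- pls_cv(X, y, ncomp_max = hp$ncomp_max %||% 10L,
                     folds = hp$folds %||% 5L, seed = seed)
        ncomp <- cv$best
      }
      pls_fit(X, y, ncomp = ncomp)
    },
    svm = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = hp$kernel %||% "radial",
                     cost = hp$cost %||% 10,
                     epsilon = hp$epsilon %||% 0.01,
                     gamma = hp$gamma %||% (1 / ncol(X))),
    rf = {
      set.seed(as.integer(seed))
      randomForest::randomForest(
        x = X, y = y,
        ntree = hp$ntree %||% 500L,
        mtry = hp$mtry %||% max(1L, floor(ncol(X) / 3)),
        nodesize = hp$nodesize %||% 5L)
    })
  structure(list(family = family, fit = fit, p = ncol(X),
                 hyperparams = hp, seed = seed),
            class = "tea_regressor")
}

#' @export
print.tea_regressor <- function(x, ...) {
  cat(sprintf("Regression model [%s], %d predictor bands\n", x$family, x$p))
  invisible(x)
}

#' @rdname fit_regressor
#' @param object a `tea_regressor`.
#' @param newdata matrix with the training band count.
#' @param ... unused.
#' @export
predict.tea_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    abort("newdata has %d columns; model was trained on %d bands",
          ncol(newdata), object$p)
  as.numeric(predict(object$fit, newdata))
}

#' Cross-validated RMSE for any model family
#'
#' Seeded K-fold partition; the model is refit on each training fold and
#' out-of-fold predictions are pooled:
#' RMSECV = sqrt(mean of pooled squared errors).
#'
#' @param family model family (see [fit_regressor()]).
#' @param X,y data.
#' @param folds number of folds, between 2 and n.
#' @param seed seed for the partition (and fold refits).
#' @param hyperparams passed to [fit_regressor()].
#' @return RMSECV (scalar).
#' @export
cross_validate <- function(family, X, y, folds = 5L, seed = 1L,
                           hyperparams = list()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) abort("folds must lie in [2, n]")
  assign <- make_folds(n, folds, seed)
  if (min(table(assign)) < 1L) abort("a fold has no samples")
  pred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    te <- assign == k
    fit <- fit_regressor(family, X[!te, , drop = FALSE], y[!te],
                         hyperparams = hyperparams, seed = seed + k)
    pred[te] <- predict(fit, X[te, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}
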
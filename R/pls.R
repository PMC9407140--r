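#' Partial least squares regression (single response)
#'
#' PLS1 with the classical sequential (NIPALS-style) component extraction:
#' predictors and response are mean-centered, then for each latent component
#' the weight vector \eqn{w_a \propto X_a^T y}, score \eqn{t_a = X_a w_a},
#' loading \eqn{p_a = X_a^T t_a / t_a^T t_a} and response loading
#' \eqn{q_a = y^T t_a / t_a^T t_a} are computed and \eqn{X} deflated by
#' \eqn{t_a p_a^T}.  For a single response no iteration is needed: each
#' component is obtained in closed form.  The regression vector for `a`
#' components is \eqn{b_a = W_a (P_a^T W_a)^{-1} q_a}, and predictions are
#' \eqn{\hat y = \bar y + (X - \bar X) b}.  With `ncomp = rank(X)`, fitted
#' values coincide with ordinary least squares.
#'
#' Extraction stops early (with a message) if the residual weight norm falls
#' below `tol`, i.e. X carries no further covariance with y.
#'
#' @param X numeric predictor matrix (n x p), finite.
#' @param y numeric response of length n with positive variance.
#' @param ncomp number of latent components, at most `min(n - 1, p)`
#'   (default `min(10, n - 1, p)`).
#' @param tol numerical tolerance for early stopping.
#' @return object of class `pls1`: list with `coefficients` (regression
#'   vector at `ncomp`), `coef_path` (p x ncomp matrix of regression
#'   vectors for 1..ncomp components), `intercept`, `x_mean`, `y_mean`,
#'   `scores`, `loadings`, `weights`, `ncomp`, `fitted.values`,
#'   `residuals`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(20, sd = 0.1)
#' fit <- pls_fit(X, y, ncomp = 3)
#' coef(fit)
#' @export
pls_fit <- function(X, y, ncomp = NULL, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (anyNA(X) || any(!is.finite(X)) || any(!is.finite(y)))
    abort("X and y must be finite with no missing values")
  if (sd(y) == 0) abort("response has zero variance; PLS undefined")
  max_comp <- min(n - 1L, p)
  if (is.null(ncomp)) ncomp <- min(10L, max_comp)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > max_comp)
    abort("ncomp must lie in [1, min(n - 1, p)] = [1, %d]", max_comp)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yc)[, 1L]
    wn <- sqrt(sum(w^2))
    if (wn < tol) {
      message(sprintf("pls_fit: stopped after %d component(s); no residual covariance",
                      a - 1L))
      break
    }
    w <- w / wn
    t <- as.vector(Xd %*% w)
    tt <- sum(t^2)
    if (tt < tol) break
    pv <- crossprod(Xd, t)[, 1L] / tt
    qa <- sum(yc * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) abort("no PLS component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  # regression vectors for every truncation 1..a_used
  coef_path <- matrix(0, p, a_used)
  PtW <- crossprod(P, W)                 # upper triangular by construction
  for (a in seq_len(a_used)) {
    ra <- seq_len(a)
    coef_path[, a] <- W[, ra, drop = FALSE] %*%
      solve(PtW[ra, ra, drop = FALSE], q[ra])
  }
  b <- coef_path[, a_used]
  fitted <- y_mean + as.vector(sweep(X, 2L, x_mean) %*% b)
  structure(list(coefficients = b, coef_path = coef_path,
                 intercept = y_mean - sum(x_mean * b),
                 x_mean = x_mean, y_mean = y_mean,
                 scores = Tm, loadings = P, weights = W, y_loadings = q,
                 ncomp = a_used, fitted.values = fitted,
                 residuals = y - fitted, y = y, n = n, p = p),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS regression: %d samples, %d predictors, %d latent component(s)\n",
              x$n, x$p, x$ncomp))
  cat(sprintf("  training RMSE %.4g, R^2 %.4f\n",
              sqrt(mean(x$residuals^2)),
              1 - sum(x$residuals^2) / sum((x$y - mean(x$y))^2)))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, ncomp = object$ncomp, ...) {
  object$coef_path[, ncomp]
}

#' Predict from a fitted PLS model
#'
#' @param object a [pls_fit()] object.
#' @param newdata matrix with the training band count.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (missing(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    abort("newdata has %d columns; model was trained on %d bands",
          ncol(newdata), object$p)
  b <- object$coef_path[, ncomp]
  object$y_mean + as.vector(sweep(newdata, 2L, object$x_mean) %*% b)
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
summary.pls1 <- function(object, ...) {
  # training fit at a components is y_mean + T[, 1:a] %*% q[1:a]
  sst <- sum((object$y - mean(object$y))^2)
  per <- vapply(seq_len(object$ncomp), function(a) {
    fit_a <- object$y_mean +
      as.vector(object$scores[, seq_len(a), drop = FALSE] %*%
                  object$y_loadings[seq_len(a)])
    r <- object$y - fit_a
    c(RMSE = sqrt(mean(r^2)), R2 = 1 - sum(r^2) / sst)
  }, numeric(2))
  out <- list(ncomp = object$ncomp, per_component = t(per))
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, ...) {
  cat("PLS fit quality by number of components:\n")
  print(round(x$per_component, 4))
  invisible(x)
}

#' Cross-validated RMSE for PLS over component counts
#'
#' Seeded K-fold cross-validation: one PLS fit per fold at `ncomp_max`
#' components, out-of-fold predictions pooled for every truncation
#' 1..ncomp_max.  `best` is the component count minimizing RMSECV (ties go
#' to fewer components).
#'
#' @param X,y training data.
#' @param ncomp_max largest component count to evaluate (capped at
#'   `min(n_train_fold - 1, p)`).
#' @param folds number of folds (default 5), between 2 and n.
#' @param seed seed for the fold assignment.
#' @return list with `rmsecv` (vector over component counts) and `best`.
#' @export
pls_cv <- function(X, y, ncomp_max = 10L, folds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) abort("folds must lie in [2, n]")
  set.seed(as.integer(seed))
  assign <- sample(rep(seq_len(folds), length.out = n))
  ncomp_max <- min(ncomp_max, ncol(X), n - ceiling(n / folds) - 1L)
  ncomp_max <- max(1L, ncomp_max)
  press <- matrix(NA_real_, n, ncomp_max)
  for (k in seq_len(folds)) {
    tr <- assign != k
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr],
                   ncomp = min(ncomp_max, sum(tr) - 1L, ncol(X)))
    for (a in seq_len(fit$ncomp))
      press[!tr, a] <- y[!tr] - predict(fit, X[!tr, , drop = FALSE], ncomp = a)
    # if extraction stopped early, reuse the deepest available component
    if (fit$ncomp < ncomp_max)
      for (a in (fit$ncomp + 1L):ncomp_max)
        press[!tr, a] <- press[!tr, fit$ncomp]
  }
  rmsecv <- sqrt(colMeans(press^2))
  list(rmsecv = rmsecv, best = which.min(rmsecv))
}
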
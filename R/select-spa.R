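#' Successive projections algorithm (SPA)
#'
#' Selects wavelengths with minimal collinearity.  For every start band j
#' and every subset size m in the configured range, a chain is grown by
#' successive orthogonal projections: at each step the not-yet-picked band
#' whose column has the largest norm after projecting out the span of the
#' already-picked columns is added (ties go to the smallest index).
#' Each candidate chain (j, m) is scored by the K-fold RMSECV of an
#' ordinary least-squares regression of y on the selected bands; the chain
#' with minimal RMSECV wins, ties resolved toward smaller m, then smaller
#' start index.  Columns are mean-centered internally before the
#' projections.
#'
#' If the residual norms collapse (rank deficiency) before a chain reaches
#' the maximal size, the chain is truncated at the last informative step.
#'
#' @param X predictor matrix (n x p), `p >=` the maximal subset size.
#' @param y response vector.
#' @param config a [selector_config()]; uses `spa_size` and `cv_folds`.
#' @param seed seed for the CV fold assignment (the projections themselves
#'   are deterministic).
#' @return a [band_selection()] whose diagnostics hold the winning start /
#'   size, the per-start best RMSECV, and the full chain of the winner.
#' @param wavelengths optional axis for reporting (defaults to band index).
#' @export
spa <- function(X, y, config = selector_config(), seed = 1L,
                wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  m_min <- config$spa_size[1]; m_max <- min(config$spa_size[2], p, n - 2L)
  if (m_min > m_max)
    abort("SPA subset size range [%d, %d] infeasible for n = %d, p = %d",
          config$spa_size[1], config$spa_size[2], n, p)
  folds <- config$cv_folds
  if (n < folds) abort("SPA needs n >= cv_folds")
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  Xc <- sweep(X, 2L, colMeans(X))
  assign <- make_folds(n, folds, seed)
  chains <- spa_chains(Xc, m_max)
  best <- list(rmsecv = Inf, m = NA_integer_, start = NA_integer_)
  start_scores <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    chain <- chains[[j]]
    if (length(chain) < m_min) next
    rms <- spa_cv_prefix(X, y, chain, assign, folds, m_min)
    sizes <- m_min:length(chain)
    start_scores[j] <- min(rms)
    for (i in seq_along(sizes)) {
      r <- rms[i]
      if (r < best$rmsecv ||
          (r == best$rmsecv && (sizes[i] < best$m ||
                                (sizes[i] == best$m && j < best$start)))) {
        best <- list(rmsecv = r, m = sizes[i], start = j)
      }
    }
  }
  if (!is.finite(best$rmsecv)) abort("SPA found no feasible chain")
  sel <- chains[[best$start]][seq_len(best$m)]
  band_selection("spa", sel, wavelengths,
                 diagnostics = list(rmsecv = best$rmsecv, size = best$m,
                                    start = best$start,
                                    start_scores = start_scores,
                                    chain = chains[[best$start]]))
}

# grow the projection chain from every start column; Xc is mean-centered.
# returns a list of index vectors (possibly shorter than m_max if the
# residual norms collapse).
spa_chains <- function(Xc, m_max, tol = 1e-10) {
  p <- ncol(Xc)
  norm0 <- colSums(Xc^2)
  lapply(seq_len(p), function(j) {
    Xd <- Xc
    chain <- integer(m_max)
    chain[1L] <- j
    for (step in seq_len(m_max)) {
      u <- Xd[, chain[step]]
      uu <- sum(u^2)
      if (uu < tol * max(norm0)) {        # picked column numerically null
        chain <- chain[seq_len(step - 1L)]
        break
      }
      if (step == m_max) break
      # deflate every column by its projection on u
      Xd <- Xd - tcrossprod(u, crossprod(u, Xd)[1L, ] / uu)
      norms <- colSums(Xd^2)
      norms[chain[seq_len(step)]] <- -Inf
      nxt <- which.max(norms)             # ties -> smallest index
      if (norms[nxt] < tol * max(norm0)) {
        chain <- chain[seq_len(step)]
        break
      }
      chain[step + 1L] <- nxt
    }
    chain[chain != 0L]
  })
}

# K-fold RMSECV of OLS on every prefix of 'chain' with size >= m_min.
# one QR per fold: prefix models are nested, so coefficients for size m
# come from backsolving the leading m+1 triangle.
spa_cv_prefix <- function(X, y, chain, assign, folds, m_min) {
  n <- nrow(X)
  mm <- length(chain)
  sizes <- m_min:mm
  sq_err <- matrix(0, n, length(sizes))
  for (k in seq_len(folds)) {
    te <- assign == k
    Ztr <- cbind(1, X[!te, chain, drop = FALSE])
    Zte <- cbind(1, X[te, chain, drop = FALSE])
    qrz <- qr(Ztr)
    R <- qr.R(qrz)
    qty <- qr.qty(qrz, y[!te])[seq_len(mm + 1L)]
    for (i in seq_along(sizes)) {
      m <- sizes[i]
      cols <- seq_len(m + 1L)
      b <- backsolve(R[cols, cols, drop = FALSE], qty[cols])
      pred <- Zte[, cols, drop = FALSE] %*% b
      sq_err[te, i] <- (y[te] - pred)^2
    }
  }
  sqrt(colMeans(sq_err))
}

#' Brute-force greedy successive-projection chain (reference oracle)
#'
#' Independent re-derivation of the SPA chain used for verification: at
#' every step it explicitly orthogonalizes all remaining columns against
#' the span of the picked ones (via QR) and takes the argmax residual norm.
#' Quadratic-cost reference; intended for small p.
#'
#' @param X predictor matrix (columns are mean-centered internally).
#' @param start start column index.
#' @param m chain length.
#' @return integer vector of column indices (length <= m).
#' @export
spa_chain_bruteforce <- function(X, start, m) {
  Xc <- sweep(as.matrix(X), 2L, colMeans(X))
  p <- ncol(Xc)
  chain <- start
  while (length(chain) < m) {
    Q <- qr.Q(qr(Xc[, chain, drop = FALSE]))
    rest <- setdiff(seq_len(p), chain)
    resid_norm <- vapply(rest, function(j) {
      v <- Xc[, j]
      r <- v - Q %*% crossprod(Q, v)
      sum(r^2)
    }, 0)
    if (max(resid_norm) < 1e-10 * max(colSums(Xc^2))) break
    chain <- c(chain, rest[which.max(resid_norm)])
  }
  chain
}
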
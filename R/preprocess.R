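#' Multiplicative scatter correction (MSC)
#'
#' Removes per-sample multiplicative and additive scatter by regressing each
#' spectrum on a reference spectrum (OLS: \eqn{x_i \approx a_i \cdot ref +
#' b_i}) and returning \eqn{(x_i - b_i) / a_i}.  After correction, each
#' spectrum regresses on the reference with slope 1 and intercept 0.  The
#' reference defaults to the column-mean spectrum of the input; holding the
#' reference fixed makes the operation idempotent.
#'
#' @param x a [spectrum_matrix()] (>= 2 bands).
#' @param reference reference spectrum (length n_bands); default column
#'   means of `x`.
#' @param tol minimum |slope|; a flatter spectrum trips an error naming the
#'   sample.
#' @return a `spectrum_matrix` with the correction applied; per-sample
#'   slopes and intercepts attached as `attr(, "msc_coef")`.
#' @export
msc <- function(x, reference = NULL, tol = 1e-8) {
  stopifnot(inherits(x, "spectrum_matrix"))
  v <- x$values
  if (ncol(v) < 2L) abort("MSC needs at least 2 bands")
  ref <- if (is.null(reference)) colMeans(v) else as.numeric(reference)
  if (length(ref) != ncol(v))
    abort("reference length (%d) does not match band count (%d)",
          length(ref), ncol(v))
  rc <- ref - mean(ref)
  ss <- sum(rc^2)
  if (ss < tol) abort("reference spectrum is flat; MSC undefined")
  a <- as.vector(v %*% rc) / ss                      # per-sample OLS slope
  b <- rowMeans(v) - a * mean(ref)                   # per-sample intercept
  low <- abs(a) < tol
  if (any(low))
    abort("MSC slope below tolerance for sample(s): %s",
          paste(rownames(v)[low], collapse = ", "))
  out <- (v - b) / a
  res <- spectrum_matrix(out, x$wavelengths, x$meta, domain = x$domain,
                         steps = c(x$steps, "msc"))
  attr(res, "msc_coef") <- data.frame(sample_id = x$meta$sample_id,
                                      slope = a, intercept = b)
  res
}

#' Savitzky--Golay smoothing
#'
#' Per-sample local least-squares polynomial smoothing with an odd window.
#' Boundary points are handled by evaluating the polynomial fits of the
#' first/last windows (so polynomials of degree <= `polyorder` are
#' reproduced exactly everywhere).  The band count is preserved.
#'
#' @param x a [spectrum_matrix()].
#' @param window odd window length, `polyorder < window <= n_bands`
#'   (default 11).
#' @param polyorder polynomial order (default 3).
#' @return a smoothed `spectrum_matrix`.
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 3L) {
  stopifnot(inherits(x, "spectrum_matrix"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  p <- ncol(x$values)
  if (window %% 2L == 0L) abort("S-G window must be odd, got %d", window)
  if (window > p) abort("S-G window (%d) exceeds band count (%d)", window, p)
  if (polyorder >= window)
    abort("S-G polynomial order (%d) must be < window (%d)", polyorder, window)
  if (polyorder < 0L) abort("S-G polynomial order must be >= 0")
  sm <- t(apply(x$values, 1L, signal::sgolayfilt, p = polyorder, n = window))
  spectrum_matrix(sm, x$wavelengths, x$meta, domain = x$domain,
                  steps = c(x$steps, sprintf("sg(%d,%d)", window, polyorder)))
}

#' First-derivative spectrum (forward difference)
#'
#' The plain forward difference over wavelength,
#' \deqn{dy/d\lambda = (y_{i+1} - y_i) / \Delta\lambda,}
#' used to remove additive baseline offsets and sharpen overlapping peaks.
#' This is deliberately the finite difference, not a Savitzky--Golay
#' derivative.  The output has one band fewer; its axis is the interval
#' midpoints (unbiased localization of the difference).  Units are per nm.
#'
#' @param x a [spectrum_matrix()] with >= 2 bands.
#' @return a `spectrum_matrix` with `n_bands - 1` columns on the midpoint
#'   axis.
#' @export
first_derivative <- function(x) {
  stopifnot(inherits(x, "spectrum_matrix"))
  v <- x$values
  if (ncol(v) < 2L) abort("first derivative needs at least 2 bands")
  dl <- diff(x$wavelengths)
  dv <- (v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]) /
    matrix(dl, nrow(v), length(dl), byrow = TRUE)
  mid <- (x$wavelengths[-1L] + x$wavelengths[-length(x$wavelengths)]) / 2
  spectrum_matrix(dv, mid, x$meta, domain = x$domain,
                  steps = c(x$steps, "d1"))
}

#' Apply a preprocessing chain
#'
#' Applies an ordered combination of the three pretreatments --
#' multiplicative scatter correction (`"msc"`), first derivative (`"d1"`),
#' Savitzky--Golay smoothing (`"sg"`) -- to a spectrum matrix.  The default
#' order `msc -> d1 -> sg` is the combined chain used throughout the
#' package; any order is accepted.  By default the chain operates on
#' absorbance (a reflectance matrix is converted with \eqn{A = -\log R}
#' first); set `chain_domain = "reflectance"` to preprocess reflectance
#' directly.  The applied steps are recorded in the output's `steps` field
#' and in the CSV comment header on export.
#'
#' @param x a [spectrum_matrix()].
#' @param steps character vector, nonempty, from `c("msc", "d1", "sg")`.
#' @param window,polyorder Savitzky--Golay settings (defaults 11 and 3).
#' @param reference optional fixed MSC reference spectrum.
#' @param chain_domain domain the chain operates in (default absorbance).
#' @return the preprocessed `spectrum_matrix`.
#' @examples
#' d <- simulate_tea_dataset(seed = 1)
#' pp <- apply_chain(d$spectra)
#' pp$steps
#' @export
apply_chain <- function(x, steps = c("msc", "d1", "sg"), window = 11L,
                        polyorder = 3L, reference = NULL,
                        chain_domain = c("absorbance", "reflectance")) {
  stopifnot(inherits(x, "spectrum_matrix"))
  chain_domain <- match.arg(chain_domain)
  if (!length(steps)) abort("preprocessing chain must be nonempty")
  bad <- setdiff(steps, c("msc", "d1", "sg"))
  if (length(bad)) abort("unknown preprocessing step(s): %s",
                         paste(bad, collapse = ", "))
  out <- if (chain_domain == "absorbance") as_absorbance(x) else x
  for (s in steps) {
    out <- switch(s,
      msc = {
        if (ncol(out$values) < 2L)
          abort("msc requested with fewer than 2 bands remaining")
        msc(out, reference = reference)
      },
      d1 = first_derivative(out),
      sg = savitzky_golay(out, window = window, polyorder = polyorder))
  }
  out
}
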
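#' Plateau-based withering/fermentation degree judgment
#'
#' The processing-degree rule: the watched quality component (FAA during
#' withering, TPs during fermentation) is tracked over time, and the stage
#' is judged *moderate* once the content has stabilized.  Concretely, a
#' trailing window of `window` time points is stable when its max - min is
#' at most `tolerance` times the overall range of the series; the verdict
#' at each evaluated time point is whether any trailing window ending at or
#' before it was stable (so once moderate, always moderate), and the
#' reported onset is the *first* time point of the earliest stable window
#' -- the start of the plateau.
#'
#' On the default noise-free trajectories this detects moderate withering
#' at the 16 h FAA plateau and moderate fermentation at the 3 h TPs
#' plateau.
#'
#' @param values content series (%) at successive time points.
#' @param times time points (hours), same length as `values`.
#' @param stage `"withering"` (watched analyte FAA) or `"fermentation"`
#'   (watched analyte TPs); recorded in the result.
#' @param window number of trailing time points that must be stable
#'   (default 3, >= 2, <= series length).
#' @param tolerance stability tolerance as a fraction of the overall series
#'   range (default 0.05).
#' @return object of class `degree_judgment`: list with `stage`, `analyte`,
#'   `times`, `verdict` (`"not-reached"`/`"moderate"` per evaluated point),
#'   `reached`, `onset_h` (plateau start, `NA` if never reached).
#' @examples
#' faa <- c(seq(4.3, 6.0, length.out = 16), rep(6.0, 3))
#' judge_degree(faa, 1:19, "withering")$onset_h   # 16
#' @export
judge_degree <- function(values, times = seq_along(values),
                         stage = c("withering", "fermentation"),
                         window = 3L, tolerance = 0.05) {
  stage <- match.arg(stage)
  window <- as.integer(window)
  n <- length(values)
  if (length(times) != n) abort("values and times must have equal length")
  if (window < 2L) abort("window must be >= 2 time points")
  if (window > n) abort("window (%d) exceeds series length (%d)", window, n)
  rng <- max(values) - min(values)
  stable <- vapply(window:n, function(i) {
    w <- values[(i - window + 1L):i]
    (max(w) - min(w)) <= tolerance * rng
  }, logical(1))
  stable <- cumsum(stable) > 0L        # monotone: once stable, stays stable
  reached <- any(stable)
  onset <- if (reached) times[(window:n)[which(stable)[1L]] - window + 1L]
           else NA_real_
  structure(list(
    stage = stage,
    analyte = if (stage == "withering") "FAA" else "TPs",
    times = times,
    eval_times = times[window:n],
    verdict = ifelse(stable, "moderate", "not-reached"),
    reached = reached, onset_h = onset,
    window = window, tolerance = tolerance),
    class = "degree_judgment")
}

#' @export
print.degree_judgment <- function(x, ...) {
  cat(sprintf("Degree judgment [%s, watching %s]: ", x$stage, x$analyte))
  if (x$reached)
    cat(sprintf("moderate %s reached; plateau onset at %g h\n", x$stage, x$onset_h))
  else
    cat("not reached over the evaluated series\n")
  invisible(x)
}
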
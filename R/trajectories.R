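#' Sampling schedule for withering and fermentation
#'
#' The study design this package emulates: during withering, leaves are
#' sampled once per hour for 19 hours; during fermentation, once every half
#' hour for 10 time points; 4 replicates each time, giving 76 + 40 = 116
#' samples in total.
#'
#' @param stage `"withering"`, `"fermentation"`, or `"both"` (default).
#' @param replicates replicates per time point (default 4).
#' @return data.frame with columns `sample_id`, `stage` (factor, withering
#'   before fermentation), `time_h`, `replicate`.
#' @examples
#' nrow(sampling_schedule())          # 116
#' nrow(sampling_schedule("withering"))  # 76
#' @export
sampling_schedule <- function(stage = c("both", "withering", "fermentation"),
                              replicates = 4L) {
  stage <- match.arg(stage)
  replicates <- as.integer(replicates)
  if (replicates < 1L) abort("replicates must be >= 1")
  mk <- function(st, times, prefix) {
    g <- expand.grid(replicate = seq_len(replicates), time_h = times)
    data.frame(
      sample_id = sprintf("%s%02d_r%d", prefix,
                          rep(seq_along(times), each = replicates), g$replicate),
      stage = st, time_h = g$time_h, replicate = g$replicate,
      stringsAsFactors = FALSE)
  }
  out <- switch(stage,
    withering    = mk("withering", 1:19, "W"),
    fermentation = mk("fermentation", seq(0.5, 5, by = 0.5), "F"),
    both = rbind(mk("withering", 1:19, "W"),
                 mk("fermentation", seq(0.5, 5, by = 0.5), "F")))
  out$stage <- factor(out$stage, levels = c("withering", "fermentation"))
  out
}

#' Trajectory parameters for the quality components
#'
#' Piecewise-linear mean trajectories of the three quality components over
#' processing time, plus per-replicate biological scatter and per-sample
#' assay (measurement) noise, all in dry-mass %.  The default shapes encode
#' the qualitative kinetics of black-tea processing: during withering TPs
#' fall steadily from 1 to 16 h then plateau, FAA rises to a maximum at 16 h
#' then plateaus, CAF stays flat; during fermentation TPs drop sharply to a
#' minimum at 3 h then plateau while FAA and CAF stay flat.  Default levels
#' are chosen so the pooled concentrations stay inside the `envelopes`
#' (TPs 6.00--13.28 %, FAA 4.11--6.13 %, CAF 4.21--5.52 %).
#'
#' Each per-analyte, per-stage entry has fields `start` and `end` (mean level
#' %, before onset / after offset), `onset` and `offset` (hours bounding the
#' linear change), `rep_sd` (replicate scatter SD, %; real composition
#' differences that do show up in the spectra) and `meas_sd` (assay
#' measurement noise SD, %; does not show up in the spectra).
#'
#' @param envelopes named list of length-2 ranges the generated
#'   concentrations must stay within.
#' @return nested list of class `trajectory_params`.
#' @export
trajectory_params <- function(envelopes = list(TPs = c(6.00, 13.28),
                                               FAA = c(4.11, 6.13),
                                               CAF = c(4.21, 5.52))) {
  tp <- function(start, end, onset, offset, rep_sd, meas_sd)
    list(start = start, end = end, onset = onset, offset = offset,
         rep_sd = rep_sd, meas_sd = meas_sd)
  structure(list(
    withering = list(
      TPs = tp(12.90, 10.60, 1, 16, 0.12, 0.06),
      FAA = tp(4.30, 6.00, 1, 16, 0.05, 0.04),
      CAF = tp(4.90, 4.90, 1, 16, 0.30, 0.10)),
    fermentation = list(
      TPs = tp(10.40, 6.35, 0.5, 3, 0.12, 0.06),
      FAA = tp(5.05, 5.05, 0.5, 3, 0.05, 0.04),
      CAF = tp(4.80, 4.80, 0.5, 3, 0.30, 0.10)),
    envelopes = envelopes), class = "trajectory_params")
}

# mean level of one analyte at time t (piecewise linear)
traj_mean <- function(par, t) {
  ifelse(t <= par$onset, par$start,
    ifelse(t >= par$offset, par$end,
      par$start + (par$end - par$start) * (t - par$onset) /
        (par$offset - par$onset)))
}

#' Simulate reference-chemistry trajectories
#'
#' Draws per-sample TPs/FAA/CAF contents for a sampling schedule: the
#' piecewise-linear stage trajectory, plus replicate scatter (latent leaf
#' composition) plus assay measurement noise.  The latent composition --
#' what the spectra actually respond to -- is attached as
#' `attr(, "latent")`; the returned columns are the "measured" values a
#' wet-lab assay would report.
#'
#' @param schedule data.frame from [sampling_schedule()].
#' @param params [trajectory_params()] object.
#' @param seed integer RNG seed (required; the draw is reproducible).
#' @param noise_scale multiplier on both noise SDs; 0 gives the noise-free
#'   mean trajectories exactly.
#' @param strict if `TRUE`, concentrations outside the envelopes raise an
#'   error; default clips to the envelope with a warning reporting the count.
#' @return data.frame (`chemistry_table`) with schedule columns plus
#'   `TPs`, `FAA`, `CAF` in dry-mass %; attribute `latent` holds the
#'   noise-free-assay composition matrix used for spectral synthesis.
#' @examples
#' chem <- simulate_trajectories(sampling_schedule(), seed = 1)
#' nrow(chem)   # 116
#' @export
simulate_trajectories <- function(schedule, params = trajectory_params(),
                                  seed, noise_scale = 1, strict = FALSE) {
  if (missing(seed)) abort("simulate_trajectories() requires an explicit seed")
  stopifnot(all(c("stage", "time_h", "replicate") %in% names(schedule)))
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  analytes <- c("TPs", "FAA", "CAF")
  latent <- measured <- matrix(NA_real_, n, 3, dimnames = list(NULL, analytes))
  n_clip <- 0L
  for (a in analytes) {
    mu <- numeric(n)
    rep_sd <- meas_sd <- numeric(n)
    for (st in c("withering", "fermentation")) {
      idx <- schedule$stage == st
      if (!any(idx)) next
      par <- params[[st]][[a]]
      mu[idx] <- traj_mean(par, schedule$time_h[idx])
      rep_sd[idx] <- par$rep_sd
      meas_sd[idx] <- par$meas_sd
    }
    lat <- mu + rnorm(n, 0, rep_sd * noise_scale)
    mea <- lat + rnorm(n, 0, meas_sd * noise_scale)
    env <- params$envelopes[[a]]
    if (!is.null(env)) {
      out <- lat < env[1] | lat > env[2] | mea < env[1] | mea > env[2]
      if (any(out)) {
        if (strict)
          abort("%d %s values fall outside the envelope [%g, %g]",
                sum(out), a, env[1], env[2])
        n_clip <- n_clip + sum(out)
        lat <- pmin(pmax(lat, env[1]), env[2])
        mea <- pmin(pmax(mea, env[1]), env[2])
      }
    }
    latent[, a] <- lat
    measured[, a] <- mea
  }
  if (n_clip > 0L)
    warning(sprintf("%d concentration draws clipped to their envelopes", n_clip))
  out <- cbind(schedule, as.data.frame(measured))
  attr(out, "latent") <- latent
  class(out) <- c("chemistry_table", "data.frame")
  out
}

#' Write / read a chemistry table as CSV
#'
#' Plain CSV with header `sample_id, stage, time_h, replicate, TPs, FAA, CAF`.
#' The latent-composition attribute is not serialized (it is a property of
#' the simulation, not of a measured dataset).
#'
#' @param chem chemistry table data.frame.
#' @param path file path.
#' @return `read_chemistry` returns a `chemistry_table` data.frame.
#' @export
write_chemistry <- function(chem, path) {
  cols <- c("sample_id", "stage", "time_h", "replicate", "TPs", "FAA", "CAF")
  write.csv(as.data.frame(chem)[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chemistry
#' @export
read_chemistry <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "time_h", "replicate", "TPs", "FAA", "CAF")
  if (!all(need %in% names(out)))
    abort("chemistry CSV must have columns: %s", paste(need, collapse = ", "))
  out$stage <- factor(out$stage, levels = c("withering", "fermentation"))
  class(out) <- c("chemistry_table", "data.frame")
  out
}
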
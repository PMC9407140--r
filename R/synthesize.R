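#' Instrumental noise model for spectral synthesis
#'
#' Per-sample distortions applied on top of exact Beer--Lambert mixing:
#' a multiplicative scatter slope and additive offset in absorbance, a linear
#' baseline drift over wavelength, and i.i.d. detector noise added in
#' reflectance.  With `mult_range = c(1, 1)`, the other ranges at `c(0, 0)`
#' and `noise_sd = 0`, synthesis is exact Beer--Lambert mixing.
#'
#' @param mult_range range of the per-sample multiplicative scatter slope.
#' @param offset_range range of the per-sample additive offset (AU).
#' @param drift_range range of the per-sample linear baseline-drift slope
#'   (AU per nm, applied relative to the axis midpoint).
#' @param noise_sd SD of i.i.d. noise added to unit reflectance.
#' @param reflectance_floor reflectance values below this are clipped up to
#'   it (count reported via message).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(mult_range = c(0.96, 1.04),
                        offset_range = c(-0.015, 0.015),
                        drift_range = c(-3e-5, 3e-5),
                        noise_sd = 2e-4,
                        reflectance_floor = 1e-6) {
  stopifnot(length(mult_range) == 2, length(offset_range) == 2,
            length(drift_range) == 2, noise_sd >= 0, reflectance_floor > 0)
  structure(list(mult_range = sort(mult_range),
                 offset_range = sort(offset_range),
                 drift_range = sort(drift_range),
                 noise_sd = noise_sd,
                 reflectance_floor = reflectance_floor),
            class = "noise_model")
}

# a noise model with every distortion switched off (exact Beer-Lambert)
#' @rdname noise_model
#' @export
noise_model_none <- function() {
  noise_model(mult_range = c(1, 1), offset_range = c(0, 0),
              drift_range = c(0, 0), noise_sd = 0)
}

#' Synthesize reflectance spectra from chemistry (Beer--Lambert forward model)
#'
#' For sample i with concentrations \eqn{c_{ik}} and pure-component profiles
#' \eqn{s_k(\lambda)}, absorbance is
#' \eqn{A_i(\lambda) = m_i \sum_k c_{ik} s_k(\lambda) + o_i + d_i(\lambda - \bar\lambda)}
#' with per-sample scatter slope \eqn{m_i}, offset \eqn{o_i} and drift
#' \eqn{d_i} drawn from the noise model; reflectance is \eqn{R = \exp(-A)}
#' (mapped into [0, 1]) with i.i.d. detector noise added and a positive
#' floor applied.  Library components not present in the chemistry table
#' (interferents) get concentrations drawn uniformly per sample: from the
#' matching entry of `interferent_ranges` when one is named, otherwise from
#' `interferent_range`.  The default `matrix` range is narrow (0.95--1.05)
#' because the dry-leaf background is nearly constant per unit mass.  The
#' spectra respond to the sample's latent leaf composition
#' (`attr(chem, "latent")`) when present; otherwise to the table's columns.
#'
#' @param chem chemistry table (see [simulate_trajectories()]).
#' @param lib [pure_component_library][make_pure_spectra] whose analyte
#'   components all appear in `chem`.
#' @param noise [noise_model()].
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param interferent_range fallback concentration range for library
#'   components not in the chemistry table.
#' @param interferent_ranges named list of per-component ranges overriding
#'   the fallback.
#' @return a reflectance-domain [spectrum_matrix()].
#' @export
synthesize_spectra <- function(chem, lib = default_component_library(),
                               noise = noise_model(), seed,
                               interferent_range = c(0.5, 1.5),
                               interferent_ranges = list(matrix = c(0.95, 1.05))) {
  if (missing(seed)) abort("synthesize_spectra() requires an explicit seed")
  stopifnot(inherits(lib, "pure_component_library"),
            inherits(noise, "noise_model"))
  comps <- colnames(lib$profiles)
  analytes <- intersect(comps, names(chem))
  if (!length(analytes))
    abort("no library component matches a chemistry column")
  set.seed(as.integer(seed))
  n <- nrow(chem)
  latent <- attr(chem, "latent")
  conc <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  for (a in analytes) {
    conc[, a] <- if (!is.null(latent) && a %in% colnames(latent))
      latent[, a] else chem[[a]]
  }
  for (k in setdiff(comps, analytes)) {
    rng <- interferent_ranges[[k]] %||% interferent_range
    conc[, k] <- runif(n, rng[1], rng[2])
  }
  A <- conc %*% t(lib$profiles)                      # n x bands
  wl <- lib$wavelengths
  m <- runif(n, noise$mult_range[1], noise$mult_range[2])
  o <- runif(n, noise$offset_range[1], noise$offset_range[2])
  d <- runif(n, noise$drift_range[1], noise$drift_range[2])
  A <- A * m + o + outer(d, wl - mean(wl))
  R <- exp(-A)
  if (noise$noise_sd > 0)
    R <- R + matrix(rnorm(length(R), 0, noise$noise_sd), n)
  n_clip <- sum(R < noise$reflectance_floor | R > 1)
  if (n_clip > 0)
    message(sprintf("synthesize_spectra: %d reflectance values clipped to [floor, 1]",
                    n_clip))
  R <- pmin(pmax(R, noise$reflectance_floor), 1)
  meta <- as.data.frame(chem)[, intersect(
    c("sample_id", "stage", "time_h", "replicate"), names(chem)), drop = FALSE]
  if (is.null(meta$sample_id)) meta$sample_id <- sprintf("S%03d", seq_len(n))
  spectrum_matrix(R, wl, meta, domain = "reflectance")
}

#' Simulate a complete tea withering/fermentation dataset
#'
#' One-call default scenario: the 116-sample schedule, the default
#' trajectories and pure-component library, and the default noise model.
#' All randomness derives from `seed`.
#'
#' @param seed integer seed.
#' @param schedule sampling schedule (default: the full 116-sample design).
#' @param params trajectory parameters.
#' @param lib pure-component library.
#' @param noise noise model.
#' @param noise_scale multiplier on the chemistry noise SDs.
#' @return list with `chemistry` (chemistry_table) and `spectra`
#'   (reflectance spectrum_matrix).
#' @examples
#' d <- simulate_tea_dataset(seed = 1)
#' dim(d$spectra)   # 116 360
#' @export
simulate_tea_dataset <- function(seed, schedule = sampling_schedule(),
                                 params = trajectory_params(),
                                 lib = default_component_library(),
                                 noise = noise_model(), noise_scale = 1) {
  if (missing(seed)) abort("simulate_tea_dataset() requires an explicit seed")
  seed <- as.integer(seed)
  chem <- simulate_trajectories(schedule, params, seed = seed,
                                noise_scale = noise_scale)
  spectra <- synthesize_spectra(chem, lib, noise, seed = seed + 1L)
  list(chemistry = chem, spectra = spectra)
}

#' Read a simulation scenario configuration
#'
#' A scenario is a small YAML (or JSON) file with a mandatory `seed` and
#' optional overrides: `n_bands`, `replicates`, `noise_scale`, and the
#' noise-model fields (`mult_range`, `offset_range`, `drift_range`,
#' `noise_sd`).  [simulate_scenario()] materializes it.
#'
#' @param path path to the YAML/JSON scenario file.
#' @return the scenario as a list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$seed)) abort("scenario file must contain a seed")
  sc
}

#' @rdname read_scenario
#' @param scenario a scenario list as returned by [read_scenario()].
#' @export
simulate_scenario <- function(scenario) {
  wl <- spectral_axis(scenario$n_bands %||% 360L)
  nm <- noise_model(
    mult_range   = scenario$mult_range   %||% c(0.96, 1.04),
    offset_range = scenario$offset_range %||% c(-0.015, 0.015),
    drift_range  = scenario$drift_range  %||% c(-3e-5, 3e-5),
    noise_sd     = scenario$noise_sd     %||% 2e-4)
  simulate_tea_dataset(
    seed = scenario$seed,
    schedule = sampling_schedule(replicates = scenario$replicates %||% 4L),
    lib = default_component_library(wl),
    noise = nm,
    noise_scale = scenario$noise_scale %||% 1)
}
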
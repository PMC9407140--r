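---
title: "Hyperspectral monitoring of tea quality components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral monitoring of tea quality components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaspec)
```

## The problem

During black-tea processing, two stages decide much of the final quality:
*withering* (slow moisture loss and enzyme activation, sampled here hourly
over 19 h) and *fermentation* (polyphenol-oxidase driven oxidation, sampled
every half hour over 5 h).  The conventional way to judge when a stage is
"moderate" is either a tea master's eye or wet-lab assays of the three key
quality components — tea polyphenols (TPs), free amino acids (FAA) and
caffeine (CAF), all expressed as dry-mass fractions in percent.  Both are
slow.  `teaspec` implements the alternative: calibrate regression models
that predict the three components from visible/near-infrared hyperspectral
images (360 bands, 391–1010 nm), then judge the processing degree from the
predicted content trajectories.

The package covers the whole chain:

1. **Cube correction** — raw digital-number (DN) cubes are converted to
   reflectance with the black/white reference correction
   \(R = dn_{max}(R_0 - B)/(W - B)\), and a region-of-interest mean gives
   one spectrum per sample (`correct_reflectance()`, `extract_roi_mean()`).
2. **Reference chemistry** — the assay equations and standard curves that
   produce the regression targets (`tps_content()`, `faa_content()`,
   `caf_content()`, `fit_standard_curve()`).
3. **Preprocessing** — multiplicative scatter correction, the forward-
   difference first derivative, and Savitzky–Golay smoothing
   (`apply_chain()`).
4. **Characteristic-band selection** — SPA, CARS and UVE (`spa()`,
   `cars()`, `uve()`).
5. **Regression and evaluation** — PLS (implemented in-package), SVM and
   random forest, scored by RC², RMSEC, RMSECV, RP², RMSEP and the
   relative predictive deviation RPD (`run_pipeline()`).
6. **Degree judgment** — the plateau rule on the watched component
   (`judge_degree()`).

Because no public dataset of this kind exists, the package ships a
synthetic-data generator (`simulate_tea_dataset()`) that reproduces the
statistical structure the analysis assumes; all tests and the acceptance
script run against it.

## The forward model behind the generator

Spectra are synthesized by Beer–Lambert mixing.  Sample \(i\) with
component concentrations \(c_{ik}\) (dry-mass %) gets the absorbance

\[
A_i(\lambda) = m_i \sum_k c_{ik}\, s_k(\lambda) + o_i +
d_i(\lambda - \bar\lambda),
\qquad R_i(\lambda) = e^{-A_i(\lambda)} + \varepsilon_{i\lambda},
\]

where \(s_k\) are nonnegative pure-component absorptivity profiles (sums of
Gaussian peaks), \(m_i, o_i, d_i\) are per-sample multiplicative scatter,
additive offset and linear baseline drift, and \(\varepsilon\) is i.i.d.
detector noise in reflectance.  With all distortions at zero the map from
chemistry to absorbance is exactly linear — the property the superposition
and least-squares-recovery tests exercise.

The default component library holds five profiles:

* the three analytes, each with a handful of Gaussian peaks.  Each analyte
  owns one narrow, semi-isolated peak (CAF at 405 nm, FAA at 452 nm, TPs'
  distinctive 705 nm shoulder) plus broader overlapping features.  The
  narrow peaks matter: axis-aligned learners such as random forests need
  at least one band where the analyte dominates, which is also how real
  absorption fingerprints behave;
* `pigment`, an interfering absorber whose concentration varies randomly
  per sample — it is what makes band selection a non-trivial problem;
* `matrix`, a broad near-constant background standing for the dry leaf
  itself.  It dominates total absorbance (~1.5 AU), which keeps the
  per-sample amplitude spread small.  This is not cosmetic: multiplicative
  scatter correction divides each spectrum by its regression slope against
  the reference, and if chemistry (rather than scatter) drives the
  amplitude, that division becomes a strong nonlinearity that destroys the
  weak-analyte signal.  A dominant constant matrix keeps MSC doing what it
  is meant to do.

Peak positions are a package design choice; no physical band assignment is
claimed, and the acceptance surface is parameter recovery, not spectral
realism.

## Trajectories and noise

Concentration trajectories are piecewise linear per stage
(`trajectory_params()`): during withering TPs fall from 12.9 % to 10.6 %
between 1 h and 16 h and then plateau, FAA rises from 4.3 % to 6.0 % with
its maximum at 16 h, CAF stays flat at 4.9 %; during fermentation TPs fall
steeply from 10.4 % to 6.35 % reaching the minimum at 3 h, while FAA and
CAF stay flat.  All draws are clipped to fixed envelopes
(TPs 6.00–13.28 %, FAA 4.11–6.13 %, CAF 4.21–5.52 %), so the pooled data
match the concentration ranges such studies report.

Two noise layers are deliberately separated:

* **replicate scatter** (`rep_sd`): real composition differences between
  replicate samples.  These *are* reflected in the spectra;
* **measurement noise** (`meas_sd`): wet-lab assay error on the reference
  values.  This is *not* in the spectra.

The chemistry table contains the measured values; the latent composition
is what `synthesize_spectra()` responds to.  The consequence is a realistic
accuracy ceiling: a model can never predict the assay error, so the
prediction-set R² is bounded by
\(\mathrm{rep}^2/(\mathrm{rep}^2 + \mathrm{meas}^2)\) for a flat
trajectory.  CAF (flat at 4.8–4.9 %, `rep_sd` 0.30, `meas_sd` 0.10) is
therefore the worst-predicted analyte by construction, mirroring how such
models rank in practice; TPs, with the largest real variation, is the
best.

The default detector noise (`noise_sd = 2e-4` reflectance units) was
calibrated once so that the CARS–PLS calibration on the default scenario
lands in the intended performance regime (prediction-set R² around 0.9 or
better for TPs), and then frozen.  It is a config knob
(`noise_model()`), not a constant of nature.

What the generator does **not** emulate: spatial leaf texture, wavelength-
correlated detector noise, nonlinear detector response, moisture-driven
continuum shifts, or any real tea absorption assignments.  Passing tests
therefore demonstrate that the algorithms are implemented correctly and
that the pipeline recovers known structure — not that these exact numbers
would be obtained on real leaves.

## Preprocessing decisions

The default chain is `msc → d1 → sg`, applied to absorbance
\(A = -\log R\):

* the chain operates on absorbance because derivative preprocessing of
  Beer–Lambert data is linear there; a reflectance-domain switch exists
  (`chain_domain`);
* the first derivative is the plain forward difference
  \((y_{i+1} - y_i)/\Delta\lambda\) — deliberately not a Savitzky–Golay
  derivative — and its output axis is the interval midpoints, which
  localizes the difference without bias.  Downstream band selections on
  derivative spectra therefore report midpoint wavelengths;
* Savitzky–Golay defaults to window 11, polynomial order 3.  The window is
  a compromise: wide enough to suppress detector noise (≈ 3× variance
  reduction), narrow enough (≈ 17 nm) not to blur the narrowest analyte
  peaks.  Both are exposed;
* MSC's reference defaults to the mean spectrum of the matrix being
  corrected; a fixed external reference can be supplied (and makes MSC
  exactly idempotent).

## Band selection decisions

The three selectors follow their original formulations; every constant is
exposed in `selector_config()`:

* **SPA** grows chains of maximally non-collinear bands by successive
  orthogonal projections from every possible start band, then scores each
  (start, size) candidate by 5-fold RMSECV of an ordinary least-squares
  fit; sizes 5–30 are searched.  Ties prefer smaller subsets, then smaller
  start indices.  A brute-force greedy oracle
  (`spa_chain_bruteforce()`) re-derives chains by explicit QR
  orthogonalization and is tested to agree exactly.
* **CARS** runs 50 Monte Carlo iterations: each fits PLS on a random 80 %
  sample subset, ranks bands by |coefficient|, enforces the exponentially
  decreasing retention schedule (`cars_schedule()`, closed form from all
  bands down to exactly 2), then applies adaptive reweighted sampling —
  p weighted draws with replacement, unique survivors kept.  The run whose
  survivor set minimizes 5-fold RMSECV wins.  The ARS stage can be
  disabled, which makes a run deterministic given the subset seed.
* **UVE** appends as many tiny-amplitude uniform noise bands as real ones,
  refits PLS leave-one-out, and computes the coefficient stability
  mean/sd per band; the cutoff is the 99th percentile of the noise bands'
  |stability|.  The PLS dimension is chosen once by CV (or fixed via
  `uve_ncomp` when the latent dimension is known, as in planted
  simulations).  If nothing clears the cutoff, the single most stable band
  is kept with a warning.

On the default scenario UVE retains by far the most bands and SPA/CARS the
fewest — the ordering such comparisons consistently report — and
PLS on CARS- or SPA-selected bands achieves cross-validation error no
worse than the full spectrum.

## Modelling and evaluation decisions

PLS is implemented in-package (`pls_fit()`) because it is both the
headline model and the engine inside CARS and UVE: single-response
sequential component extraction, closed-form per component, with the
full coefficient path stored so one fit serves all truncations (used
heavily by the cross-validation helpers).  At full rank it reproduces
ordinary least squares; tests also cross-check predictions against an
independent implementation.  SVM (`e1071`) and random forest
(`randomForest`) enter through the thin `fit_regressor()` contract, as is
standard practice.

Evaluation follows the usual calibration/prediction vocabulary: RC²/RMSEC
on the 4:1 training split, RMSECV by seeded 5-fold CV on the training set,
RP²/RMSEP on the held-out test set, and RPD = sd(test)/RMSEP with the
"poor model" flag below 1.4.  R² is defined as 1 − SSE/SST (not squared
correlation); the identity RPD·RMSEP = sd(test) holds to machine precision
on every report row.  Band selection sees the training samples only — a
deliberate strengthening against information leakage, verified by a test
that permutes test-set chemistry and checks that no selected band changes.

The degree judgment implements the plateau rule: the watched component
(FAA for withering, TPs for fermentation) is "stable" at a time point when
the trailing window of 3 points spans at most 5 % of the series range; the
reported onset is the first point of the earliest stable window, and the
verdict is monotone (once moderate, always moderate).  Window and
tolerance are parameters; on noise-free default trajectories the rule
fires at 16 h (withering) and 3 h (fermentation), the change points the
trajectories encode.

## Numerical choices and degenerate inputs

* `dn_max` defaults to 65,552 — the camera's stated DN ceiling, kept
  verbatim although it is not \(2^{16}-1\); it is configurable, and the
  ENVI writer switches between uint16 and uint32 storage accordingly.
* Corrected reflectance outside \([0, dn_{max}]\) (specular pixels) is
  retained, not clipped; only W = B pixels are masked invalid.  Clipping
  would bias ROI means.
* The CARS schedule guards its ceiling against floating-point fuzz so the
  endpoints (all bands, then exactly 2) are exact.
* PLS stops extracting components when the residual weight norm vanishes
  (rank deficiency) and says so; zero-variance responses are an error.
* Concentration draws outside the envelopes are clipped with a warning by
  default (`strict = TRUE` turns this into an error), keeping the sample
  count fixed.
* Ties in CV-based choices always resolve toward the simpler model
  (fewer components, fewer bands, smaller start index).

## Problem sizes used by the tests

The test-suite defaults keep everything desk-sized: the full 116 × 360
scenario for the end-to-end checks (one full 3 × 3 × 3 grid plus a
10-seed CARS/SPA–PLS recovery study), 60-band scenarios for pipeline
plumbing tests, and planted regressions of 100 × 200 (UVE) and 80 × 100
over 20 seeds (CARS) for the selector oracles.  The whole suite runs in a
few minutes on one CPU.

## Known limitations

* Synthetic Gaussian signatures, not measured tea spectra; conclusions
  about real-leaf performance require real calibration data.
* SVR and RF hyperparameters use fixed sensible defaults; no tuning grids.
* The judgment rule is the plateau heuristic, not a classifier; it
  presumes the watched component's trajectory actually plateaus.
* `read_cube()` supports exactly one ENVI dialect (BSQ, little-endian,
  unsigned integers) by design.
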
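test_that("pure-component profiles are Gaussian sums with the stated properties", {
  wl <- spectral_axis(120)
  lib <- make_pure_spectra(wl, list(
    A = data.frame(center = 700, width = 30, height = 1)))
  expect_equal(which.max(lib$profiles[, "A"]), which.min(abs(wl - 700)))

  zero <- make_pure_spectra(wl, list(Z = data.frame(center = 500, width = 10,
                                                    height = 0)))
  expect_true(all(zero$profiles == 0))

  # two peaks equal the sum of the single-peak profiles
  two <- make_pure_spectra(wl, list(
    AB = data.frame(center = c(500, 800), width = c(20, 40),
                    height = c(0.5, 0.7))))
  p1 <- make_pure_spectra(wl, list(A = data.frame(center = 500, width = 20,
                                                  height = 0.5)))
  p2 <- make_pure_spectra(wl, list(B = data.frame(center = 800, width = 40,
                                                  height = 0.7)))
  expect_equal(two$profiles[, 1], p1$profiles[, 1] + p2$profiles[, 1])

  expect_error(make_pure_spectra(wl, list(A = data.frame())), "no peaks")
  expect_error(make_pure_spectra(wl, list(A = data.frame(center = 200,
                                                         width = 10,
                                                         height = 1))),
               "outside")
})

test_that("default library is well-conditioned and nonnegative", {
  lib <- default_component_library()
  expect_true(all(lib$profiles >= 0))
  kap <- kappa(lib$profiles[, c("TPs", "FAA", "CAF")], exact = TRUE)
  expect_true(is.finite(kap))
  expect_lt(kap, 100)
})

test_that("sampling schedule matches the two-stage study design", {
  s <- sampling_schedule()
  expect_equal(nrow(s), 116L)
  expect_equal(sum(s$stage == "withering"), 76L)
  expect_equal(sum(s$stage == "fermentation"), 40L)
  expect_equal(sort(unique(s$time_h[s$stage == "withering"])), as.numeric(1:19))
  expect_equal(sort(unique(s$time_h[s$stage == "fermentation"])),
               seq(0.5, 5, by = 0.5))
  expect_false(anyDuplicated(s$sample_id) > 0)
})

test_that("noise-free trajectories have the documented kinetics", {
  sched <- sampling_schedule()
  chem <- simulate_trajectories(sched, seed = 3, noise_scale = 0)
  wi <- chem[chem$stage == "withering" & chem$replicate == 1, ]
  wi <- wi[order(wi$time_h), ]
  # TPs monotone nonincreasing over 1-16 h then flat
  expect_true(all(diff(wi$TPs[wi$time_h <= 16]) <= 0))
  expect_lt(wi$TPs[wi$time_h == 16], wi$TPs[wi$time_h == 1])
  expect_equal(wi$TPs[wi$time_h >= 16], rep(wi$TPs[wi$time_h == 16], 4))
  # FAA nondecreasing with maximum at 16 h
  expect_true(all(diff(wi$FAA[wi$time_h <= 16]) >= 0))
  expect_equal(which.max(wi$FAA), which(wi$time_h == 16))
  # CAF constant
  expect_equal(diff(range(wi$CAF)), 0)
  fe <- chem[chem$stage == "fermentation" & chem$replicate == 1, ]
  fe <- fe[order(fe$time_h), ]
  expect_true(all(diff(fe$TPs[fe$time_h <= 3]) <= 0))
  expect_equal(fe$TPs[fe$time_h >= 3], rep(min(fe$TPs), 5))
  expect_equal(diff(range(fe$FAA)), 0)
  expect_equal(diff(range(fe$CAF)), 0)
})

test_that("generated concentrations respect the envelopes at any seed", {
  for (seed in 1:5) {
    chem <- suppressWarnings(
      simulate_trajectories(sampling_schedule(), seed = seed))
    expect_true(all(chem$TPs >= 6.00 & chem$TPs <= 13.28))
    expect_true(all(chem$FAA >= 4.11 & chem$FAA <= 6.13))
    expect_true(all(chem$CAF >= 4.21 & chem$CAF <= 5.52))
  }
  expect_error(simulate_trajectories(
    sampling_schedule(),
    params = trajectory_params(envelopes = list(TPs = c(10, 11))),
    seed = 1, strict = TRUE), "envelope")
})

test_that("spectral synthesis is exact Beer-Lambert with noise off", {
  wl <- spectral_axis(80)
  lib <- make_pure_spectra(wl, list(
    TPs = data.frame(center = 550, width = 40, height = 0.05),
    FAA = data.frame(center = 700, width = 30, height = 0.04),
    CAF = data.frame(center = 850, width = 25, height = 0.03)))
  chem <- simulate_trajectories(sampling_schedule(), seed = 2, noise_scale = 0)
  sm <- synthesize_spectra(chem, lib, noise_model_none(), seed = 9)
  A <- -log(sm$values)
  conc <- attr(chem, "latent")
  # one-component proportionality and 3-analyte OLS recovery
  expected <- conc %*% t(lib$profiles)
  expect_lt(max(abs(A - expected)), 1e-10)
  rec <- t(qr.solve(lib$profiles, t(A)))
  expect_lt(max(abs(rec - conc) / pmax(conc, 1)), 1e-8)
})

test_that("synthesis is linear in absorbance space (superposition)", {
  wl <- spectral_axis(50)
  lib <- make_pure_spectra(wl, list(
    TPs = data.frame(center = 500, width = 30, height = 0.05),
    FAA = data.frame(center = 650, width = 30, height = 0.04),
    CAF = data.frame(center = 800, width = 30, height = 0.03)))
  sched <- sampling_schedule()[1:6, ]
  for (seed in 1:3) {
    set.seed(seed * 101)
    mk <- function(vals) {
      ch <- cbind(sched, as.data.frame(vals))
      class(ch) <- c("chemistry_table", "data.frame")
      ch
    }
    v1 <- matrix(runif(18, 4, 10), 6, dimnames = list(NULL, c("TPs", "FAA", "CAF")))
    v2 <- matrix(runif(18, 4, 10), 6, dimnames = list(NULL, c("TPs", "FAA", "CAF")))
    a <- function(ch) -log(synthesize_spectra(ch, lib, noise_model_none(),
                                              seed = 5)$values)
    lhs <- a(mk(v1 + v2))
    expect_equal(lhs, a(mk(v1)) + a(mk(v2)), tolerance = 1e-10)
  }
})

test_that("same seed gives bit-identical datasets", {
  d1 <- suppressWarnings(simulate_tea_dataset(seed = 11))
  d2 <- suppressWarnings(simulate_tea_dataset(seed = 11))
  expect_identical(d1$spectra$values, d2$spectra$values)
  expect_identical(d1$chemistry$TPs, d2$chemistry$TPs)
  d3 <- suppressWarnings(simulate_tea_dataset(seed = 12))
  expect_false(identical(d1$spectra$values, d3$spectra$values))
})

test_that("default dataset has the study dimensions", {
  d <- suppressWarnings(simulate_tea_dataset(seed = 4))
  expect_equal(dim(d$spectra), c(116L, 360L))
  expect_equal(range(d$spectra$wavelengths), c(391, 1010))
  expect_true(all(d$spectra$values > 0 & d$spectra$values <= 1))
})

test_that("scenario files round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_bands: 60", "noise_sd: 0.001"), path)
  sc <- read_scenario(path)
  expect_equal(sc$seed, 5)
  d <- suppressWarnings(simulate_scenario(sc))
  expect_equal(ncol(d$spectra$values), 60L)
  writeLines("n_bands: 60", path)
  expect_error(read_scenario(path), "seed")
})
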
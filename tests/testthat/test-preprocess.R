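test_that("MSC removes per-sample affine distortion exactly", {
  set.seed(1)
  p <- 40
  base <- sin(seq(0, 3, length.out = p)) + 2
  n <- 6
  a <- runif(n, 0.5, 2); b <- runif(n, -1, 1)
  distorted <- outer(a, base) + b
  wl <- spectral_axis(p, c(400, 900))
  meta <- data.frame(sample_id = sprintf("S%d", 1:n))
  x <- spectrum_matrix(distorted, wl, meta, domain = "absorbance")
  corrected <- msc(x, reference = base)
  expect_lt(max(abs(sweep(corrected$values, 2, base))), 1e-10)
  # sample equal to the reference is unchanged
  xr <- spectrum_matrix(rbind(base, base + 0), wl,
                        data.frame(sample_id = c("r1", "r2")),
                        domain = "absorbance")
  expect_equal(msc(xr, reference = base)$values[1, ], base,
               ignore_attr = TRUE)
  # x = 2*ref + 3 maps onto ref exactly
  x23 <- spectrum_matrix(rbind(2 * base + 3, base),
                         wl, data.frame(sample_id = c("a", "b")),
                         domain = "absorbance")
  expect_equal(msc(x23, reference = base)$values[1, ], base,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("MSC post-condition and idempotence hold", {
  x <- toy_spectra(n = 8, p = 30, seed = 4)
  ref <- colMeans(x$values)
  out <- msc(x, reference = ref)
  # regressing each corrected spectrum on the reference: slope 1, intercept 0
  for (i in 1:8) {
    fit <- lm(out$values[i, ] ~ ref)
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-10)
    expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-10)
  }
  again <- msc(out, reference = ref)
  expect_equal(again$values, out$values, tolerance = 1e-10)
  # flat spectrum trips a named error
  flat <- x
  flat$values[3, ] <- 5
  expect_error(msc(flat, reference = ref), "S03")
})

test_that("Savitzky-Golay reproduces low-order polynomials and smooths noise", {
  p <- 60
  wl <- spectral_axis(p, c(400, 1000))
  meta <- data.frame(sample_id = "s1")
  # constant spectrum unchanged
  const <- spectrum_matrix(matrix(3, 1, p), wl, meta, domain = "absorbance")
  expect_equal(savitzky_golay(const)$values, const$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  # exact cubic in band index, polyorder 3: reproduced at every band
  i <- seq_len(p)
  cubic <- 1e-4 * i^3 - 2e-2 * i^2 + 0.3 * i + 2
  xc <- spectrum_matrix(matrix(cubic, 1), wl, meta, domain = "absorbance")
  expect_lt(max(abs(savitzky_golay(xc, 11, 3)$values - cubic)), 1e-8)
  # white noise variance strictly reduced
  set.seed(2)
  noise <- matrix(rnorm(p), 1)
  xn <- spectrum_matrix(noise, wl, meta, domain = "absorbance")
  expect_lt(var(as.vector(savitzky_golay(xn, 11, 3)$values)),
            var(as.vector(noise)))
  expect_error(savitzky_golay(xn, 10, 3), "odd")
  expect_error(savitzky_golay(xn, 11, 11), "order")
  expect_error(savitzky_golay(xn, 61, 3), "exceeds")
})

test_that("first derivative is the forward difference over wavelength", {
  wl <- c(400, 402, 404)
  meta <- data.frame(sample_id = "s1")
  x <- spectrum_matrix(matrix(c(1, 3, 6), 1), wl, meta, domain = "absorbance")
  d <- first_derivative(x)
  expect_equal(as.vector(d$values), c(1.0, 1.5))
  expect_equal(d$wavelengths, c(401, 403))
  # constant -> zero; identity ramp -> ones
  p <- 25
  wl2 <- spectral_axis(p, c(500, 900))
  cc <- spectrum_matrix(matrix(7, 2, p),
                        wl2, data.frame(sample_id = c("a", "b")),
                        domain = "absorbance")
  expect_true(all(first_derivative(cc)$values == 0))
  ramp <- spectrum_matrix(matrix(wl2, 1), wl2, meta, domain = "absorbance")
  expect_equal(as.vector(first_derivative(ramp)$values), rep(1, p - 1))
  # derivative annihilates additive offsets
  x1 <- toy_spectra(3, 20, seed = 6)
  x2 <- x1; x2$values <- x2$values + 0.37
  expect_equal(first_derivative(x1)$values, first_derivative(x2)$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  # differencing down to a single band is rejected
  two_band <- spectrum_matrix(matrix(c(1, 2), 1, 2), c(400, 401), meta,
                              domain = "absorbance")
  expect_error(first_derivative(two_band), "2")
})

test_that("preprocessing chains validate, record steps and update the axis", {
  x <- toy_spectra(5, 30, seed = 3, domain = "reflectance")
  out <- apply_chain(x)
  expect_equal(out$steps, c("log", "msc", "d1", "sg(11,3)"))
  expect_equal(ncol(out$values), 29L)
  expect_equal(out$domain, "absorbance")
  expect_error(apply_chain(x, steps = character()), "nonempty")
  expect_error(apply_chain(x, steps = c("msc", "snv")), "unknown")
  # replicated reference spectrum is left unchanged by an msc-only chain
  wl <- spectral_axis(20, c(400, 800))
  base <- exp(-seq(1, 2, length.out = 20))
  xr <- spectrum_matrix(rbind(base, base, base), wl,
                        data.frame(sample_id = c("a", "b", "c")),
                        domain = "absorbance")
  same <- apply_chain(xr, steps = "msc", chain_domain = "reflectance")
  expect_equal(same$values, xr$values, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the combined chain shrinks inter-replicate scatter on drifting data", {
  # replicate pairs with multiplicative + offset + drift distortions
  d <- suppressWarnings(simulate_tea_dataset(seed = 8,
    noise = noise_model(mult_range = c(0.9, 1.1),
                        offset_range = c(-0.05, 0.05),
                        drift_range = c(-1e-4, 1e-4), noise_sd = 0)))
  raw <- as_absorbance(d$spectra)
  pp <- apply_chain(d$spectra, steps = c("msc", "d1", "sg"))
  # within-replicate-group distance relative to the overall spread:
  # replicates share chemistry, so preprocessing that removes per-sample
  # distortions must make them relatively closer
  rep_ratio <- function(v, meta) {
    key <- paste(meta$stage, meta$time_h)
    g <- split(seq_len(nrow(v)), key)
    within <- mean(vapply(g, function(idx)
      mean(dist(v[idx, , drop = FALSE])), 0))
    within / mean(dist(v))
  }
  expect_lt(rep_ratio(pp$values, pp$meta), rep_ratio(raw$values, raw$meta))
})
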
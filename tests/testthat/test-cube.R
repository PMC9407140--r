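test_that("black/white correction implements the reflectance formula", {
  wl <- spectral_axis(3, c(400, 700))
  mk <- function(v) hyperspec_cube(array(v, c(2, 2, 3)), wl)
  w <- mk(1000); b <- mk(200)
  # fixed points
  expect_true(all(correct_reflectance(mk(1000), w, b)$values == 65552))
  expect_true(all(correct_reflectance(mk(200), w, b)$values == 0))
  # direct arithmetic: 65552 * 400 / 800
  expect_true(all(correct_reflectance(mk(600), w, b)$values == 32776))
})

test_that("correction masks W = B pixels and keeps out-of-range values", {
  wl <- spectral_axis(2, c(400, 500))
  raw <- hyperspec_cube(array(500, c(2, 2, 2)), wl)
  wdat <- array(1000, c(2, 2, 2)); wdat[1, 1, ] <- 200
  w <- hyperspec_cube(wdat, wl)
  b <- hyperspec_cube(array(200, c(2, 2, 2)), wl)
  ri <- correct_reflectance(raw, w, b)
  expect_false(ri$valid[1, 1])
  expect_true(all(ri$valid[-1]))
  expect_true(all(is.na(ri$values[1, 1, ])))
  # specular pixel: R0 > W is retained, not clipped
  raw2dat <- array(500, c(2, 2, 2)); raw2dat[2, 2, ] <- 1200
  ri2 <- correct_reflectance(hyperspec_cube(raw2dat, wl), w, b)
  expect_gt(ri2$values[2, 2, 1], 65552)
  expect_equal(ri2$n_out_of_range, 2L)
  # all-invalid references error
  expect_error(correct_reflectance(raw, b, b), "all pixels invalid")
  expect_error(correct_reflectance(raw, w,
    hyperspec_cube(array(200, c(3, 3, 2)), wl)), "shape")
})

test_that("correction is affine per pixel in the raw cube", {
  wl <- spectral_axis(4, c(400, 800))
  set.seed(5)
  w <- hyperspec_cube(array(sample(900:1200, 36, TRUE), c(3, 3, 4)), wl)
  b <- hyperspec_cube(array(sample(100:200, 36, TRUE), c(3, 3, 4)), wl)
  r0 <- array(runif(36, 300, 800), c(3, 3, 4))
  for (a in c(0.25, 0.5, 0.9)) {
    mixed <- a * r0 + (1 - a) * b$data
    lhs <- correct_reflectance(hyperspec_cube(mixed, wl), w, b)$values
    rhs <- a * correct_reflectance(hyperspec_cube(r0, wl), w, b)$values
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("ROI mean is the per-band average over masked pixels", {
  wl <- spectral_axis(2, c(400, 500))
  vals <- array(0, c(2, 2, 2))
  vals[1, 1, ] <- c(10, 100); vals[2, 1, ] <- c(20, 200)
  vals[1, 2, ] <- c(30, 300); vals[2, 2, ] <- c(40, 400)
  raw <- hyperspec_cube(vals, wl, dn_max = 65552)
  w <- hyperspec_cube(array(65552, c(2, 2, 2)), wl)
  b <- hyperspec_cube(array(0, c(2, 2, 2)), wl)
  ri <- correct_reflectance(raw, w, b)
  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(extract_roi_mean(ri, one), c(10, 100))
  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(extract_roi_mean(ri, two), c(15, 150))
  expect_equal(extract_roi_mean(ri), c(25, 250))
  expect_error(extract_roi_mean(ri, matrix(FALSE, 2, 2)), "no valid pixels")
})

test_that("ROI mean commutes with correction for uniform references", {
  wl <- spectral_axis(3, c(400, 700))
  set.seed(8)
  r0 <- array(runif(27, 200, 900), c(3, 3, 3))
  w <- hyperspec_cube(array(1000, c(3, 3, 3)), wl)
  b <- hyperspec_cube(array(100, c(3, 3, 3)), wl)
  ri <- correct_reflectance(hyperspec_cube(r0, wl), w, b)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE), 3)
  roi_then <- extract_roi_mean(ri, mask)
  flat <- matrix(r0, 9, 3)
  mean_then <- 65552 * (colMeans(flat[as.vector(mask), ]) - 100) / 900
  expect_equal(roi_then, mean_then, tolerance = 1e-9)
})

test_that("cube synthesis inverts the correction within quantization", {
  set.seed(21)
  r <- runif(40, 0, 65552)
  cs <- synthesize_cube(r, shape = c(4, 5))
  # fixed points of the defaults
  top <- synthesize_cube(rep(65552, 3), shape = c(2, 2),
                         wavelengths = spectral_axis(3))
  expect_identical(top$raw$data, top$white$data)
  bot <- synthesize_cube(rep(0, 3), shape = c(2, 2),
                         wavelengths = spectral_axis(3))
  expect_identical(bot$raw$data, bot$black$data)
  ri <- correct_reflectance(cs$raw, cs$white, cs$black)
  expect_lt(max(abs(extract_roi_mean(ri) - r)), 0.5)
  expect_error(synthesize_cube(r, white_level = 0), "positive")
  expect_error(synthesize_cube(c(-5, 10)), "0, dn_max")
})

test_that("ENVI round trip is bit-exact and validates headers", {
  for (dn_max in c(65535, 65552)) {      # uint16 and uint32 paths
    cube <- toy_cube(dn_max = dn_max)
    path <- tempfile()
    write_cube(cube, path)
    back <- read_cube(path)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths, tolerance = 1e-6)
    expect_equal(back$dn_max, dn_max)
  }
  # corrupted headers give distinct errors
  cube <- toy_cube()
  path <- tempfile()
  write_cube(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(sub("bands = 3", "bands = 4", hdr), paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelength list")
  writeLines(hdr[!grepl("samples", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "samples")
  writeLines(sub("interleave = bsq", "interleave = bil", hdr),
             paste0(path, ".hdr"))
  expect_error(read_cube(path), "interleave")
  writeLines(hdr, paste0(path, ".hdr"))
  writeBin(raw(4), path)  # truncate the payload
  expect_error(read_cube(path), "size mismatch")
})

test_that("ROI masks round-trip through run-length text", {
  set.seed(3)
  mask <- matrix(runif(35) > 0.6, 5, 7)
  path <- tempfile()
  write_roi(mask, path)
  expect_identical(read_roi(path), mask)
})

test_that("spectrum matrices stack in canonical order with checks", {
  wl <- spectral_axis(5, c(400, 800))
  mk <- function(id, stage, t, r) list(spectrum = rep(t, 5), sample_id = id,
                                       stage = stage, time_h = t, replicate = r)
  samples <- list(mk("b", "fermentation", 1, 1), mk("a", "withering", 2, 1),
                  mk("c", "withering", 1, 2), mk("d", "withering", 1, 1))
  sm <- build_spectrum_matrix(samples, wl)
  expect_equal(sm$meta$sample_id, c("d", "c", "a", "b"))
  # input order does not matter
  sm2 <- build_spectrum_matrix(rev(samples), wl)
  expect_identical(sm$values, sm2$values)
  expect_equal(dim(build_spectrum_matrix(samples[1], wl)), c(1L, 5L))
  expect_error(build_spectrum_matrix(c(samples, samples[1]), wl), "duplicate")
  bad <- samples; bad[[1]]$spectrum <- 1:3
  expect_error(build_spectrum_matrix(bad, wl), "length")
})

test_that("spectrum matrix CSV round-trips values, metadata and steps", {
  d <- suppressWarnings(simulate_tea_dataset(seed = 2,
    schedule = sampling_schedule(replicates = 1),
    lib = default_component_library(spectral_axis(30))))
  pp <- apply_chain(d$spectra, steps = c("msc", "d1"))
  path <- tempfile(fileext = ".csv")
  write_spectra(pp, path)
  back <- read_spectra(path)
  expect_equal(back$values, pp$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$steps, pp$steps)
  expect_equal(back$domain, "absorbance")
  expect_equal(back$meta$sample_id, pp$meta$sample_id)
})

test_that("chemistry CSV round-trips", {
  chem <- suppressWarnings(simulate_trajectories(sampling_schedule(), seed = 6))
  path <- tempfile(fileext = ".csv")
  write_chemistry(chem, path)
  back <- read_chemistry(path)
  expect_equal(back$TPs, chem$TPs, tolerance = 1e-10)
  expect_equal(as.character(back$stage), as.character(chem$stage))
})
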
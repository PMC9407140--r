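# shared fixture builders (everything generated in code)

# small spectrum matrix with arbitrary values
toy_spectra <- function(n = 4, p = 20, seed = 1, domain = "absorbance") {
  set.seed(seed)
  wl <- spectral_axis(p, c(400, 1000))
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     stage = factor(rep("withering", n),
                                    levels = c("withering", "fermentation")),
                     time_h = seq_len(n), replicate = 1L)
  spectrum_matrix(matrix(runif(n * p, 0.2, 0.8), n, p), wl, meta,
                  domain = domain)
}

# regression problem with a handful of planted informative bands
planted_problem <- function(n = 80, p = 100, k = 5, noise_sd = 0.05,
                            seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  informative <- sort(sample.int(p, k))
  beta <- runif(k, 0.8, 1.5) * sample(c(-1, 1), k, replace = TRUE)
  y <- as.numeric(X[, informative, drop = FALSE] %*% beta + rnorm(n, 0, noise_sd))
  list(X = X, y = y, informative = informative, beta = beta)
}

# tiny deterministic cube set for I/O tests
toy_cube <- function(h = 2, w = 2, b = 3, dn_max = 65552, seed = 7) {
  set.seed(seed)
  wl <- spectral_axis(b, c(400, 700))
  hyperspec_cube(array(sample.int(1000, h * w * b, replace = TRUE),
                       c(h, w, b)), wl, dn_max = dn_max)
}

expect_all_finite <- function(x) expect_false(any(!is.finite(x)))
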
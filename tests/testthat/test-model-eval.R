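test_that("train/test split honors the 4:1 ratio and the seed", {
  ids <- sprintf("S%03d", 1:116)
  s <- split_train_test(ids, seed = 1)
  expect_length(s$train, 93L)
  expect_length(s$test, 23L)
  expect_setequal(c(s$train, s$test), ids)
  expect_length(intersect(s$train, s$test), 0L)
  s5 <- split_train_test(letters[1:5], seed = 2)
  expect_length(s5$train, 4L)
  expect_length(s5$test, 1L)
  expect_identical(split_train_test(ids, seed = 7)$test,
                   split_train_test(ids, seed = 7)$test)
  expect_false(identical(split_train_test(ids, seed = 7)$test,
                         split_train_test(ids, seed = 8)$test))
  expect_error(split_train_test(letters[1:4]), "at least 5")
  expect_error(split_train_test(c("a", "a", "b", "c", "d")), "unique")
})

test_that("model families honor the common contract", {
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.numeric(X %*% c(1, -2, 0.5, 0) + rnorm(50, sd = 0.05))
  # rf on constant y predicts the constant
  rf_const <- fit_regressor("rf", X, rep(2.5, 50) + rnorm(50, sd = 1e-12),
                            seed = 1)
  expect_equal(predict(rf_const, X[1:5, ]), rep(2.5, 5), tolerance = 1e-6)
  # svr on exactly linear data with tiny epsilon fits almost perfectly
  sv <- fit_regressor("svr", X, y, hyperparams = list(epsilon = 1e-3,
                                                      cost = 100))
  r2 <- 1 - sum((y - predict(sv, X))^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.99)
  # rf is reproducible under seed
  rf1 <- fit_regressor("rf", X, y, seed = 42)
  rf2 <- fit_regressor("rf", X, y, seed = 42)
  expect_identical(predict(rf1, X), predict(rf2, X))
  expect_error(fit_regressor("gbm", X, y), "unknown model family")
  expect_error(predict(rf1, X[, 1:2]), "trained on")
})

test_that("cross_validate pools out-of-fold errors like a hand-rolled loop", {
  set.seed(9)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5))
  got <- cross_validate("pls", X, y, folds = 5, seed = 21,
                        hyperparams = list(ncomp = 3))
  set.seed(21)
  assign <- sample(rep(1:5, length.out = n))
  pred <- numeric(n)
  for (k in 1:5) {
    tr <- assign != k
    fit <- pls_fit(X[tr, ], y[tr], ncomp = 3)
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  expect_equal(got, sqrt(mean((y - pred)^2)), tolerance = 1e-12)
  # exact linear model, LOO on collinear-free data: zero error
  expect_lt(cross_validate("pls", X, y, folds = n, seed = 3,
                           hyperparams = list(ncomp = 3)), 1e-8)
  expect_error(cross_validate("pls", X, y, folds = 1), "folds")
})

test_that("evaluation metrics satisfy their definitions and flags", {
  set.seed(30)
  Xtr <- matrix(rnorm(120), 40, 3); Xte <- matrix(rnorm(45), 15, 3)
  beta <- c(1, 2, -1)
  ytr <- as.numeric(Xtr %*% beta + rnorm(40, sd = 0.2))
  yte <- as.numeric(Xte %*% beta + rnorm(15, sd = 0.2))
  fit <- pls_fit(Xtr, ytr, ncomp = 3)
  ev <- evaluate_model(fit, Xtr, ytr, Xte, yte, rmsecv = 0.25)
  # RPD identity at machine precision
  expect_equal(ev$rpd * ev$rmsep, sd(yte), tolerance = 1e-12)
  expect_equal(ev$rp2, 1 - sum((yte - predict(fit, Xte))^2) /
                 sum((yte - mean(yte))^2), tolerance = 1e-12)
  expect_equal(ev$flag, "ok")
  # a deliberately broken model trips the poor-prediction flag
  mean_model <- structure(list(mu = mean(ytr)), class = "mean_only")
  assign("predict.mean_only",
         function(object, newdata, ...) rep(object$mu, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.mean_only", envir = globalenv()), add = TRUE)
  ev0 <- evaluate_model(mean_model, Xtr, ytr, Xte, yte)
  expect_lte(ev0$rp2, 0.05)
  expect_equal(ev0$flag, "poor")
  expect_lt(ev0$rpd, 1.4)
  # perfect predictions: R2 = 1, RMSE = 0, RPD flagged undefined
  oracle <- structure(list(beta = beta), class = "oracle_lm")
  assign("predict.oracle_lm",
         function(object, newdata, ...) as.numeric(newdata %*% object$beta),
         envir = globalenv())
  on.exit(rm("predict.oracle_lm", envir = globalenv()), add = TRUE)
  evp <- evaluate_model(oracle, Xtr, as.numeric(Xtr %*% beta),
                        Xte, as.numeric(Xte %*% beta))
  expect_equal(evp$rc2, 1)
  expect_equal(evp$rmsep, 0)
  expect_equal(evp$flag, "rpd-undefined")
  expect_true(is.na(evp$rpd))
})

test_that("degree judgment finds plateau onsets by the trailing-window rule", {
  # strictly increasing series never stabilizes
  inc <- judge_degree(seq(4, 6, length.out = 19), 1:19, "withering")
  expect_false(inc$reached)
  expect_true(all(inc$verdict == "not-reached"))
  # rise to 16 h then exactly constant: onset at the plateau start
  faa <- c(seq(4.3, 6.0, length.out = 16), rep(6.0, 3))
  j <- judge_degree(faa, 1:19, "withering", window = 3)
  expect_true(j$reached)
  expect_equal(j$onset_h, 16)
  expect_equal(j$analyte, "FAA")
  # verdict is monotone
  expect_true(all(diff(j$verdict == "moderate") >= 0))
  # all-constant series: moderate from the first evaluated window
  cst <- judge_degree(rep(5, 10), seq(0.5, 5, 0.5), "fermentation", window = 3)
  expect_true(all(cst$verdict == "moderate"))
  expect_equal(cst$onset_h, 0.5)
  expect_equal(cst$analyte, "TPs")
  expect_error(judge_degree(1:2, 1:2, "withering", window = 3), "window")
})
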
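#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs: the data source (a synthetic-scenario
#' seed or an existing dataset), the preprocessing chain, the selector and
#' model grids, and the shared evaluation settings.  All randomness in the
#' run derives from `seed`.
#'
#' @param seed master RNG seed.
#' @param data optional list with `chemistry` and `spectra` (as produced by
#'   [simulate_tea_dataset()] or read from CSV); when `NULL` the default
#'   synthetic scenario is simulated from `seed`.
#' @param analytes response columns to model.
#' @param selectors subset of `c("none", "spa", "cars", "uve")`; `"none"`
#'   is the all-bands baseline.
#' @param models subset of `c("svm", "pls", "rf")`.
#' @param steps preprocessing chain (see [apply_chain()]).
#' @param window,polyorder Savitzky--Golay settings.
#' @param ratio train:test ratio.
#' @param folds CV folds for RMSECV.
#' @param selector selector configuration ([selector_config()]).
#' @param hyperparams named list of per-family hyperparameter lists.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, data = NULL,
                            analytes = c("TPs", "FAA", "CAF"),
                            selectors = c("spa", "cars", "uve"),
                            models = c("svm", "pls", "rf"),
                            steps = c("msc", "d1", "sg"),
                            window = 11L, polyorder = 3L,
                            ratio = 4, folds = 5L,
                            selector = selector_config(),
                            hyperparams = list()) {
  bad <- setdiff(selectors, c("none", "spa", "cars", "uve"))
  if (length(bad)) abort("unknown selector(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(models, c("svm", "svr", "pls", "rf"))
  if (length(bad)) abort("unknown model(s): %s", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), data = data, analytes = analytes,
                 selectors = selectors, models = models, steps = steps,
                 window = as.integer(window), polyorder = as.integer(polyorder),
                 ratio = ratio, folds = as.integer(folds),
                 selector = selector, hyperparams = hyperparams),
            class = "pipeline_config")
}

#' Run the full calibration pipeline
#'
#' End-to-end workflow on one dataset: preprocess the spectra, split the
#' samples 4:1 into calibration and prediction sets, then for every analyte
#' x selector x model cell: select characteristic bands *on the training
#' samples only* (a deliberate guard against information leakage), fit the
#' model on the training set, compute 5-fold RMSECV on the training set,
#' and evaluate on the held-out test set.  A failing cell is recorded with
#' its error message and the rest of the grid proceeds.
#'
#' With the default three selectors, three models and three analytes the
#' report has 27 rows.  Identical configuration and seed give an identical
#' report.
#'
#' @param config a [pipeline_config()].
#' @return object of class `tea_report`: list with `metrics` (the grid as a
#'   data.frame), `selections` (named list of [band_selection()]s per
#'   analyte x selector), `predictions` (per-cell data.frames of actual vs
#'   predicted test values), `split`, `wavelengths` (post-preprocessing
#'   axis), `config`, and `errors`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 1, selectors = "cars",
#'                                     models = "pls", analytes = "TPs"))
#' rep$metrics
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- config$data %||% simulate_tea_dataset(seed = config$seed)
  chem <- data$chemistry
  spectra <- data$spectra
  pp <- apply_chain(spectra, steps = config$steps, window = config$window,
                    polyorder = config$polyorder)
  X <- pp$values
  wl <- pp$wavelengths
  ids <- pp$meta$sample_id
  chem <- as.data.frame(chem)
  if (!all(ids %in% chem$sample_id))
    abort("chemistry table does not cover all spectral samples")
  chem <- chem[match(ids, chem$sample_id), ]
  split <- split_train_test(ids, ratio = config$ratio, seed = config$seed)
  tr <- ids %in% split$train
  metrics <- list(); selections <- list(); predictions <- list()
  errors <- character()
  for (analyte in config$analytes) {
    y <- chem[[analyte]]
    if (is.null(y)) abort("analyte '%s' not in the chemistry table", analyte)
    for (sel_name in config$selectors) {
      sel <- tryCatch(
        switch(sel_name,
          none = band_selection("none", seq_along(wl), wl),
          spa  = spa(X[tr, , drop = FALSE], y[tr], config$selector,
                     seed = config$seed, wavelengths = wl),
          cars = cars(X[tr, , drop = FALSE], y[tr], config$selector,
                      seed = config$seed, wavelengths = wl),
          uve  = uve(X[tr, , drop = FALSE], y[tr], config$selector,
                     seed = config$seed, wavelengths = wl)),
        error = function(e) e)
      key_sel <- paste(analyte, sel_name, sep = ".")
      if (inherits(sel, "error")) {
        errors[key_sel] <- conditionMessage(sel)
        next
      }
      selections[[key_sel]] <- sel
      Xtr <- X[tr, sel$indices, drop = FALSE]
      Xte <- X[!tr, sel$indices, drop = FALSE]
      for (model in config$models) {
        key <- paste(analyte, sel_name, model, sep = ".")
        row <- tryCatch({
          hp <- config$hyperparams[[model]] %||% list()
          fit <- fit_regressor(model, Xtr, y[tr], hyperparams = hp,
                               seed = config$seed)
          rmsecv <- cross_validate(model, Xtr, y[tr], folds = config$folds,
                                   seed = config$seed, hyperparams = hp)
          ev <- evaluate_model(fit, Xtr, y[tr], Xte, y[!tr], rmsecv = rmsecv,
                               n_bands = sel$n_bands)
          predictions[[key]] <- data.frame(
            sample_id = ids[!tr], actual = y[!tr],
            predicted = predict(fit, Xte), stringsAsFactors = FALSE)
          cbind(data.frame(analyte = analyte, selector = sel_name,
                           model = model, stringsAsFactors = FALSE), ev)
        }, error = function(e) e)
        if (inherits(row, "error")) {
          errors[key] <- conditionMessage(row)
        } else {
          metrics[[key]] <- row
        }
      }
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, c(metrics, make.row.names = FALSE))
             else data.frame()
  structure(list(metrics = metrics, selections = selections,
                 predictions = predictions, split = split,
                 wavelengths = wl, config = config, errors = errors),
            class = "tea_report")
}

#' @export
print.tea_report <- function(x, digits = 3, ...) {
  cat(sprintf("Calibration report: %d grid cells (%d train / %d test samples)\n",
              nrow(x$metrics), length(x$split$train), length(x$split$test)))
  if (nrow(x$metrics)) {
    df <- x$metrics
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits = digits)
    print(df, row.names = FALSE)
  }
  if (length(x$errors)) {
    cat("Failed cells:\n")
    for (k in names(x$errors)) cat(sprintf("  %s: %s\n", k, x$errors[k]))
  }
  invisible(x)
}

#' Export a calibration report
#'
#' Writes the metrics grid as CSV and (optionally) the band selections and
#' test-set predictions as JSON/CSV next to it.
#'
#' @param report a `tea_report`.
#' @param path CSV path for the metrics grid.
#' @param artifacts if `TRUE`, also write `<path>.selections.json` and one
#'   predictions CSV per grid cell alongside.
#' @export
write_report <- function(report, path, artifacts = FALSE) {
  stopifnot(inherits(report, "tea_report"))
  write.csv(report$metrics, path, row.names = FALSE)
  if (artifacts) {
    jsonlite::write_json(
      lapply(report$selections, function(s)
        list(method = s$method, n_bands = s$n_bands,
             wavelengths = s$wavelengths, ranges = format_band_ranges(s))),
      paste0(path, ".selections.json"), auto_unbox = TRUE, digits = NA)
    for (k in names(report$predictions))
      write.csv(report$predictions[[k]],
                sprintf("%s.pred.%s.csv", path, k), row.names = FALSE)
  }
  invisible(path)
}
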
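#' Spectrum matrix: the pipeline's central data container
#'
#' An n_samples x n_bands matrix of spectra on a common wavelength axis with
#' per-sample metadata, plus a domain flag (`"reflectance"` on [0, 1] or
#' `"absorbance"`) and an ordered record of the preprocessing steps already
#' applied.
#'
#' @param values numeric matrix, samples in rows, bands in columns; no
#'   missing values.
#' @param wavelengths wavelength axis, length `ncol(values)`.
#' @param meta data.frame of per-sample metadata with at least a `sample_id`
#'   column (unique); typically also `stage`, `time_h`, `replicate`.
#' @param domain `"reflectance"` or `"absorbance"`.
#' @param steps character vector: preprocessing steps applied so far, in
#'   order.
#' @return object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(values, wavelengths, meta,
                            domain = c("reflectance", "absorbance"),
                            steps = character()) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  check_axis(wavelengths)
  if (ncol(values) != length(wavelengths))
    abort("values has %d columns but axis has %d wavelengths",
          ncol(values), length(wavelengths))
  if (anyNA(values) || any(!is.finite(values)))
    abort("spectrum matrix must not contain missing or non-finite values")
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(values))
    abort("metadata rows (%d) do not match sample rows (%d)",
          nrow(meta), nrow(values))
  if (is.null(meta$sample_id)) abort("metadata needs a 'sample_id' column")
  if (anyDuplicated(meta$sample_id))
    abort("duplicate sample_id in metadata: %s",
          meta$sample_id[anyDuplicated(meta$sample_id)])
  dimnames(values) <- list(meta$sample_id, sprintf("%.2f", wavelengths))
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 meta = meta, domain = domain, steps = as.character(steps)),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("Spectrum matrix: %d samples x %d bands (%.1f-%.1f nm), %s\n",
              nrow(x$values), ncol(x$values), min(x$wavelengths),
              max(x$wavelengths), x$domain))
  if (length(x$steps))
    cat("  applied steps:", paste(x$steps, collapse = " -> "), "\n")
  if (!is.null(x$meta$stage))
    print(table(stage = x$meta$stage))
  invisible(x)
}

#' @export
dim.spectrum_matrix <- function(x) dim(x$values)

#' Stack per-sample spectra into a spectrum matrix
#'
#' Assembles a list of (spectrum, metadata) records -- e.g. ROI mean spectra
#' extracted from corrected cubes -- into a [spectrum_matrix()], sorted into
#' the canonical order (stage: withering before fermentation, then time,
#' then replicate), so the result does not depend on input order.
#'
#' @param samples list; each element a list with fields `spectrum` (numeric,
#'   length of the axis), `sample_id`, `stage`, `time_h`, `replicate`.
#' @param wavelengths the shared wavelength axis.
#' @param domain domain flag for the spectra (default reflectance).
#' @return a `spectrum_matrix` of shape (length(samples), n_bands).
#' @export
build_spectrum_matrix <- function(samples, wavelengths,
                                  domain = c("reflectance", "absorbance")) {
  domain <- match.arg(domain)
  check_axis(wavelengths)
  if (!length(samples)) abort("no samples supplied")
  nb <- length(wavelengths)
  for (s in samples) {
    if (length(s$spectrum) != nb)
      abort("sample '%s': spectrum length %d does not match axis length %d",
            s$sample_id %||% "?", length(s$spectrum), nb)
  }
  meta <- data.frame(
    sample_id = vapply(samples, function(s) as.character(s$sample_id), ""),
    stage = factor(vapply(samples, function(s) as.character(s$stage), ""),
                   levels = c("withering", "fermentation")),
    time_h = vapply(samples, function(s) as.numeric(s$time_h), 0),
    replicate = vapply(samples, function(s) as.integer(s$replicate), 0L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id))
    abort("duplicate sample id: %s",
          meta$sample_id[duplicated(meta$sample_id)][1])
  ord <- order(meta$stage, meta$time_h, meta$replicate)
  values <- do.call(rbind, lapply(samples, function(s) as.numeric(s$spectrum)))
  spectrum_matrix(values[ord, , drop = FALSE], wavelengths,
                  meta[ord, , drop = FALSE], domain = domain)
}

#' Convert a spectrum matrix between reflectance and absorbance
#'
#' Absorbance is defined as the negative natural log of unit reflectance,
#' \eqn{A = -\log R}; the inverse map is \eqn{R = \exp(-A)}.  Reflectance is
#' floored at a small positive value before taking logs.
#'
#' @param x a `spectrum_matrix`.
#' @param floor minimum reflectance used when taking logs.
#' @return a `spectrum_matrix` in the other domain (no-op if already there).
#' @export
as_absorbance <- function(x, floor = 1e-6) {
  stopifnot(inherits(x, "spectrum_matrix"))
  if (x$domain == "absorbance") return(x)
  v <- -log(pmax(x$values, floor))
  spectrum_matrix(v, x$wavelengths, x$meta, domain = "absorbance",
                  steps = c(x$steps, "log"))
}

#' @rdname as_absorbance
#' @export
as_reflectance <- function(x) {
  stopifnot(inherits(x, "spectrum_matrix"))
  if (x$domain == "reflectance") return(x)
  spectrum_matrix(exp(-x$values), x$wavelengths, x$meta,
                  domain = "reflectance", steps = c(x$steps, "exp"))
}

#' Write / read a spectrum matrix as CSV
#'
#' Header row is `sample_id, stage, time_h, replicate` followed by the
#' wavelengths in nm to two decimals.  Applied preprocessing steps are
#' recorded in a leading `# applied_steps:` comment line, restored on read.
#'
#' @param x a `spectrum_matrix`.
#' @param path file path.
#' @return `read_spectra` returns a `spectrum_matrix`.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectrum_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# domain: %s", x$domain), con)
  if (length(x$steps))
    writeLines(sprintf("# applied_steps: %s", paste(x$steps, collapse = ",")), con)
  df <- cbind(x$meta[, c("sample_id", "stage", "time_h", "replicate")],
              as.data.frame(x$values, check.names = FALSE))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  domain <- sub("^# domain: *", "", grep("^# domain:", hdr, value = TRUE))
  if (!length(domain)) domain <- "reflectance"
  steps <- character()
  st <- grep("^# applied_steps:", hdr, value = TRUE)
  if (length(st))
    steps <- strsplit(sub("^# applied_steps: *", "", st[1]), ",")[[1]]
  df <- read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE,
                 stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "stage", "time_h", "replicate")
  wl <- as.numeric(setdiff(names(df), meta_cols))
  meta <- df[, meta_cols]
  meta$stage <- factor(meta$stage, levels = c("withering", "fermentation"))
  spectrum_matrix(as.matrix(df[, !(names(df) %in% meta_cols)]), wl, meta,
                  domain = domain, steps = steps)
}
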
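#' Write / read a hyperspectral cube in a minimal ENVI dialect
#'
#' One dialect only: band-sequential (BSQ) interleave, little-endian,
#' unsigned 16-bit (ENVI data type 12) or unsigned 32-bit (type 13) integers.
#' The binary goes to `path` and a text header to `path.hdr` carrying
#' `samples`, `lines`, `bands`, `data type`, `interleave`, `byte order`,
#' the wavelength list, and the DN ceiling as `dn max`.  The data type is
#' chosen from `dn_max` (16-bit when it fits in 65535).  Integer DN data
#' round-trips bit-exactly.
#'
#' @param cube a [hyperspec_cube()].
#' @param path path of the binary data file (header written alongside as
#'   `<path>.hdr`).
#' @return `read_cube` returns a `hyperspec_cube`; `write_cube` returns
#'   `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  d <- dim(cube$data)
  dtype <- if (cube$dn_max <= 65535) 12L else 13L
  size <- if (dtype == 12L) 2L else 4L
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    sprintf("data type = %d", dtype),
    "interleave = bsq",
    "byte order = 0",
    sprintf("dn max = %s", format(cube$dn_max, scientific = FALSE)),
    sprintf("wavelength = { %s }",
            paste(sprintf("%.6g", cube$wavelengths), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ, row-major within each band: sample (column) index fastest
  v <- as.integer(aperm(cube$data, c(2, 1, 3)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = size, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hpath <- paste0(path, ".hdr")
  if (!file.exists(hpath)) abort("missing header file: %s", hpath)
  if (!file.exists(path)) abort("missing data file: %s", path)
  lines <- readLines(hpath)
  getf <- function(key) {
    ln <- grep(sprintf("^%s *=", key), lines, value = TRUE)
    if (!length(ln)) abort("header missing required field '%s'", key)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  samples <- as.integer(getf("samples"))
  nlines <- as.integer(getf("lines"))
  bands <- as.integer(getf("bands"))
  dtype <- as.integer(getf("data type"))
  interleave <- tolower(getf("interleave"))
  byte_order <- as.integer(getf("byte order"))
  dn_max <- as.numeric(getf("dn max"))
  wl_txt <- sub(".*\\{", "", paste(grep("wavelength", lines, value = TRUE),
                                   collapse = " "))
  wl <- as.numeric(strsplit(gsub("[}{]", "", wl_txt), ",")[[1]])
  if (interleave != "bsq")
    abort("unsupported interleave '%s' (only bsq is supported)", interleave)
  if (byte_order != 0L) abort("unsupported byte order %d (expect 0)", byte_order)
  if (!dtype %in% c(12L, 13L))
    abort("unsupported data type %d (expect 12 = uint16 or 13 = uint32)", dtype)
  if (length(wl) != bands)
    abort("header band count (%d) does not match wavelength list length (%d)",
          bands, length(wl))
  size <- if (dtype == 12L) 2L else 4L
  n <- samples * nlines * bands
  expected <- n * size
  actual <- file.size(path)
  if (actual != expected)
    abort("data size mismatch: %d bytes on disk, %d expected from header",
          actual, expected)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = size,
               signed = (size == 4L), endian = "little")
  data <- aperm(array(as.numeric(v), c(samples, nlines, bands)), c(2, 1, 3))
  hyperspec_cube(data, wl, dn_max = dn_max)
}

#' Write / read an ROI mask as run-length text
#'
#' Tiny text format for boolean masks: first line `height width`, then one
#' line per run of `TRUE` pixels in column-major order (`start length`).
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `read_roi` returns the logical matrix.
#' @export
write_roi <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  v <- as.vector(mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  lines <- c(sprintf("%d %d", nrow(mask), ncol(mask)),
             sprintf("%d %d", starts[keep], r$lengths[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  mask <- matrix(FALSE, dims[1], dims[2])
  for (ln in lines[-1]) {
    sr <- as.integer(strsplit(ln, " ")[[1]])
    mask[sr[1] + seq_len(sr[2]) - 1L] <- TRUE
  }
  mask
}
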
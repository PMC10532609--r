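#' Read an 8-bit image (PNG, PGM or TIFF)
#'
#' @param path File path; format is chosen by extension (`.png`, `.pgm`,
#'   `.tif`/`.tiff`).
#' @return For grayscale input, an H x W numeric matrix of 0..255 values;
#'   for RGB, an H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    pgm = .read_pgm(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path) * 255
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  img
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "P5")) stop("only binary (P5) PGM is supported")
  vals <- integer(0)
  while (length(vals) < 3L) {
    ln <- readLines(con, n = 1L)
    ln <- sub("#.*", "", ln)
    vals <- c(vals, as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- vals[1L]; h <- vals[2L]; maxval <- vals[3L]
  raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
  matrix(raw, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' Write a grayscale or binary raster as PNG
#'
#' @param img Numeric matrix in 0..255 (or logical/0-1 binary mask).
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  m <- img * 1
  if (max(m) > 1) m <- m / 255
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}

#' Write a grayscale or binary raster as binary PGM (P5)
#'
#' @inheritParams write_image_png
#' @export
write_image_pgm <- function(img, path) {
  m <- img * 1
  if (max(m) <= 1) m <- m * 255
  m <- round(pmin(pmax(m, 0), 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(m), nrow(m)), "255"), con)
  writeBin(as.integer(t(m)), con, size = 1L)
  invisible(path)
}

#' Serialize a pattern grid (and optionally its codeword book) to JSON
#'
#' @param pattern A `csl_pattern`.
#' @param path Output path.
#' @export
write_pattern_json <- function(pattern, path) {
  obj <- list(
    rows = pattern$rows, cols = pattern$cols,
    symbol_px = pattern$symbol_px, gap_px = pattern$gap_px,
    seed = pattern$seed,
    labels = unclass(pattern$labels)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pattern grid from JSON written by [write_pattern_json()]
#'
#' @param path Input path.
#' @return A `csl_pattern`.
#' @export
read_pattern_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(labels = matrix(as.integer(obj$labels), obj$rows, obj$cols),
         rows = as.integer(obj$rows), cols = as.integer(obj$cols),
         symbol_px = as.integer(obj$symbol_px), gap_px = as.integer(obj$gap_px),
         seed = as.integer(obj$seed)),
    class = "csl_pattern"
  )
}
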
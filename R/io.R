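#' Read a B-scan image from PNG, TIFF or headerless RAW
#'
#' PNG and TIFF are read through \pkg{png} / \pkg{tiff}; multi-channel
#' images are converted to a single channel by averaging the colour
#' channels, with a warning. Headerless RAW is read row-major as unsigned
#' 8-bit with the geometry supplied by the caller; a byte-count mismatch is
#' rejected with a diagnostic naming the expected and actual size.
#'
#' @param path input file; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, anything else treated as RAW).
#' @param rows,cols image geometry, required for RAW.
#' @return integer matrix of grey levels 0-255.
#' @export
read_bscan <- function(path, rows = NULL, cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    return(array_to_grey(arr))
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF input")
    arr <- tiff::readTIFF(path)
    return(array_to_grey(arr))
  }
  # headerless RAW
  if (is.null(rows) || is.null(cols))
    stop("RAW input needs rows and cols")
  expected <- as.integer(rows) * as.integer(cols)
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf("RAW size mismatch: expected %d bytes (%d x %d), found %d",
                 expected, rows, cols, actual))
  bytes <- readBin(path, what = "integer", n = expected, size = 1L,
                   signed = FALSE)
  matrix(as.integer(bytes), nrow = rows, ncol = cols, byrow = TRUE)
}

array_to_grey <- function(arr) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      warning("multi-channel image converted to grey by channel averaging")
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    } else {
      arr <- arr[, , 1]
    }
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Write a B-scan as an 8-bit grey PNG
#'
#' @param image integer matrix, grey levels 0-255.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bscan <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Write / read an RPE contour as CSV
#'
#' One row per image column: `column`, `row` (1-based indices).
#'
#' @param contour integer vector of per-column RPE rows.
#' @param path CSV file.
#' @return `write_contour`: invisibly `path`; `read_contour`: integer
#'   vector.
#' @export
write_contour <- function(contour, path) {
  write.csv(data.frame(column = seq_along(contour), row = as.integer(contour)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  df <- read.csv(path)
  as.integer(df$row[order(df$column)])
}

#' Write / read a feature table as CSV
#'
#' Fixed header: `image_id`, optional `class_label` and `split`, then
#' `w1` ... `w20`. A `config_hash` column records the configuration the
#' table was produced under.
#'
#' @param features data frame as returned by [run_pipeline()].
#' @param path CSV file.
#' @return `write_features`: invisibly `path`; `read_features`: data frame.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) read.csv(path, stringsAsFactors = FALSE)
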
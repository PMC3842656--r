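#' Median filtering of a B-scan
#'
#' Replaces every pixel by the median of its `mask_rows` x `mask_cols`
#' neighborhood, the standard suppression step for the salt-and-pepper noise
#' that otherwise derails per-column brightness-maximum search. Borders are
#' handled by edge replication, which avoids introducing artificial dark
#' rims that would perturb the RPE detector.
#'
#' @param image numeric/integer matrix of grey levels.
#' @param mask_rows,mask_cols odd mask dimensions (default 3 x 3).
#' @return matrix of the same shape and storage mode as `image`.
#' @export
median_filter <- function(image, mask_rows = 3L, mask_cols = 3L) {
  image <- as_bscan(image)
  if (mask_rows %% 2L == 0L || mask_cols %% 2L == 0L)
    stop("median mask dimensions must be odd")
  if (mask_rows > nrow(image) || mask_cols > ncol(image))
    stop("median mask larger than the image")
  out <- cpp_median_filter(image * 1.0, as.integer(mask_rows),
                           as.integer(mask_cols))
  matrix(as.integer(out), nrow(image), ncol(image))
}

as_bscan <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop("image must be nonempty")
  image
}

#' Simple per-column RPE detection (brightness argmax)
#'
#' For every column, returns the row index of the maximum grey level; ties
#' are broken towards the smallest row index (the anatomically shallowest
#' position), making the result deterministic. Sensitive to residual bright
#' noise; [detect_rpe()] is the robust variant.
#'
#' @param image numeric matrix (typically the median-filtered B-scan).
#' @return integer vector of row indices, one per column (class
#'   `"rpe_contour"` attributes-free plain vector).
#' @export
detect_rpe_simple <- function(image) {
  image <- as_bscan(image)
  apply(image, 2L, which.max)
}

#' Robust per-column RPE detection (bright-cluster median)
#'
#' Per column, collects all rows whose grey level reaches at least
#' `p_r` times the column maximum and returns the median of their row
#' indices (lower median for even-sized sets, so the result is an existing
#' row). A column whose maximum is zero has no meaningful cluster and maps
#' to the sentinel value `M` (the last row); such columns are excluded from
#' downstream analysis by the validity mask.
#'
#' With `p_r = 1` the candidate set reduces to the rows achieving the exact
#' maximum, so a unique maximum reproduces [detect_rpe_simple()].
#'
#' @param image numeric matrix.
#' @param p_r cluster threshold coefficient in (0, 1]; default 0.9.
#' @return integer vector of row indices (sentinel `nrow(image)` for
#'   degenerate columns).
#' @export
detect_rpe <- function(image, p_r = 0.9) {
  image <- as_bscan(image)
  if (p_r <= 0 || p_r > 1) stop("p_r must lie in (0, 1]")
  M <- nrow(image)
  vapply(seq_len(ncol(image)), function(n) {
    col <- image[, n]
    mx <- max(col)
    if (mx <= 0) return(M)
    cand <- which(col >= p_r * mx)
    lower_median(cand)
  }, integer(1))
}

# lower median: floor of the midpoint for even counts
lower_median <- function(x) {
  x <- sort(x)
  as.integer(x[(length(x) + 1L) %/% 2L])
}

#' Blank the area above the RPE contour
#'
#' Copies pixels at rows at or below the contour and sets everything above
#' to the sentinel value -1, which unambiguously distinguishes the excluded
#' area from genuine grey level 0 beneath the RPE.
#'
#' @param image numeric matrix (median-filtered B-scan).
#' @param contour integer vector of per-column RPE rows (length `ncol`).
#' @return numeric matrix with -1 above the contour.
#' @export
build_rpe_image <- function(image, contour) {
  image <- as_bscan(image)
  check_contour(contour, image)
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  keep <- rows >= matrix(contour, nrow(image), ncol(image), byrow = TRUE)
  out <- matrix(-1, nrow(image), ncol(image))
  out[keep] <- image[keep]
  out
}

check_contour <- function(contour, image) {
  if (length(contour) != ncol(image))
    stop("contour length must equal the number of image columns")
  if (any(contour < 1L) || any(contour > nrow(image)))
    stop("contour row indices out of image range")
  invisible(contour)
}

#' Flatten the sub-RPE image to a common top row
#'
#' Shifts each column up by its contour row so the RPE sits at row 1
#' everywhere; the space trailing each column is filled with the sentinel
#' -1. This is the affine coordinate-system conversion that turns the curved
#' sub-RPE region into the rectangular choroid image analysed downstream.
#'
#' @param rpe_image numeric matrix as produced by [build_rpe_image()] (or
#'   the median-filtered image itself; only rows at/below the contour are
#'   used).
#' @param contour integer vector of per-column RPE rows.
#' @return an object of class `"flattened_choroid"`: list with `pixels`
#'   (matrix, values in 0..255 or -1), `valid_mask` (0/1 integer matrix,
#'   1 exactly where `pixels != -1`), and `contour`.
#' @export
flatten_choroid <- function(rpe_image, contour) {
  rpe_image <- as_bscan(rpe_image)
  check_contour(contour, rpe_image)
  M <- nrow(rpe_image); N <- ncol(rpe_image)
  pixels <- matrix(-1, M, N)
  for (n in seq_len(N)) {
    depth <- M - contour[n] + 1L
    pixels[seq_len(depth), n] <- rpe_image[contour[n]:M, n]
  }
  valid <- matrix(as.integer(pixels != -1), M, N)
  structure(list(pixels = pixels, valid_mask = valid, contour = contour),
            class = "flattened_choroid")
}

#' @export
print.flattened_choroid <- function(x, ...) {
  cat(sprintf("<flattened_choroid> %d x %d, %.1f%% valid\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Full preprocessing chain for one B-scan
#'
#' Median filtering, robust RPE detection, sub-RPE extraction and
#' flattening, in that order.
#'
#' @param image integer matrix, grey levels 0-255.
#' @param config a [pipeline_config()] (defaults used when `NULL`).
#' @return a `"flattened_choroid"`; the detected contour is in
#'   `$contour`.
#' @export
preprocess_bscan <- function(image, config = NULL) {
  config <- config %||% pipeline_config()
  med <- median_filter(image, config$median_mask, config$median_mask)
  contour <- detect_rpe(med, config$p_r_rpe)
  flatten_choroid(build_rpe_image(med, contour), contour)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
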
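#' Connected-component analysis of a refined scale image
#'
#' Labels the 8-connected foreground components of a binary image (objects
#' touching the border are retained) and summarizes each object: pixel
#' count, centre of gravity (`cx` = mean column, `cy` = mean row, 1-based
#' pixels) and the mean brightness of its member pixels sampled from the
#' corrected grey image.
#'
#' @param binary 0/1 matrix (typically an `L_K` scale image).
#' @param grey optional numeric matrix of the same shape (the corrected
#'   choroid residuals); when `NULL`, brightness is `NA`.
#' @return an object of class `"object_set"`: data frame with one row per
#'   object (`id`, `n_pixels`, `cx`, `cy`, `mean_brightness`) and the label
#'   matrix in attribute `"labels"`.
#' @export
label_objects <- function(binary, grey = NULL) {
  if (!is.matrix(binary) || !all(binary %in% c(0L, 1L)))
    stop("binary image required (values 0/1)")
  if (!is.null(grey) && !all(dim(grey) == dim(binary)))
    stop("grey image must match the binary image shape")
  lab <- cpp_label8(matrix(as.integer(binary), nrow(binary), ncol(binary)))
  k <- attr(lab, "n_objects")
  if (k == 0L) {
    out <- data.frame(id = integer(0), n_pixels = integer(0),
                      cx = numeric(0), cy = numeric(0),
                      mean_brightness = numeric(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- ((idx - 1L) %% nrow(binary)) + 1L
    cols <- ((idx - 1L) %/% nrow(binary)) + 1L
    n_pix <- tabulate(l, nbins = k)
    cy <- tapply(rows, l, mean)
    cx <- tapply(cols, l, mean)
    mb <- if (is.null(grey)) rep(NA_real_, k) else as.numeric(tapply(grey[idx], l, mean))
    out <- data.frame(id = seq_len(k), n_pixels = n_pix,
                      cx = as.numeric(cx), cy = as.numeric(cy),
                      mean_brightness = mb)
  }
  attr(out, "labels") <- lab
  class(out) <- c("object_set", "data.frame")
  out
}

# population standard deviation (divisor n)
pop_sd <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Names of the 20 texture features
#'
#' @return character vector `w1` ... `w20`.
#' @export
feature_names <- function() paste0("w", 1:20)

#' Extract the 20-dimensional object-texture feature vector
#'
#' For the fixed scale ladder 3, 5, 7, 9, 11 the vector collects, in order:
#'
#' * `w1`-`w5` — number of objects in the refined image per scale;
#' * `w6`-`w10` — mean object centre-of-gravity position on the x axis
#'   (columns) per scale;
#' * `w11`-`w15` — mean centre-of-gravity position on the y axis (rows)
#'   per scale;
#' * `w16`-`w20` — population standard deviation of the per-object mean
#'   brightness (sampled from the corrected grey image) per scale.
#'
#' A scale with zero objects contributes 0 to its centroid and brightness
#' entries (a complete vector is required by the classifier); a single
#' object gives brightness dispersion 0.
#'
#' @param stack a `"scale_stack"` with all five scales.
#' @param corrected a `"corrected_choroid"` (brightness source), or a plain
#'   numeric matrix.
#' @return named numeric vector of length 20 (`w1` ... `w20`).
#' @export
extract_features <- function(stack, corrected) {
  scales <- attr(stack, "scales") %||% as.integer(names(stack))
  if (length(scales) != 5L)
    stop("all five scales are required (got ", length(scales), ")")
  grey <- if (inherits(corrected, "corrected_choroid")) corrected$pixels else corrected
  w <- numeric(20)
  for (j in seq_along(scales)) {
    obj <- label_objects(stack[[j]]$L_K, grey)
    k <- nrow(obj)
    w[j] <- k
    w[5 + j] <- if (k > 0) mean(obj$cx) else 0
    w[10 + j] <- if (k > 0) mean(obj$cy) else 0
    w[15 + j] <- if (k > 0) pop_sd(obj$mean_brightness) else 0
  }
  setNames(w, feature_names())
}
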
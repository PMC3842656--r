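#' Brightness-uniformity correction of the flattened choroid
#'
#' Subtracts a local 30 x 30 windowed mean from every pixel, removing the
#' slowly varying illumination component so that only structures on the
#' scale of choroidal vessels (at most 20 x 20 pixels, hence a mean mask at
#' least twice that size) survive. Sentinel (-1) pixels are excluded from
#' the window mean via the validity mask, and the result is defined only on
#' the interior band where the full mask fits (a `mask_size/2` margin on all
#' four sides); outside the band the residual is set to 0 and masked out.
#'
#' @param choroid a `"flattened_choroid"`.
#' @param mask_size side of the square averaging mask (default 30).
#' @return an object of class `"corrected_choroid"`: list with `pixels`
#'   (signed residuals, 0 outside the mask), `valid_mask` (0/1 matrix) and
#'   `mask_size`.
#' @export
brightness_correction <- function(choroid, mask_size = 30L) {
  stopifnot(inherits(choroid, "flattened_choroid"))
  px <- choroid$pixels
  if (nrow(px) < mask_size || ncol(px) < mask_size)
    stop("image smaller than the averaging mask")
  margin <- mask_size %/% 2L
  r0 <- -margin; r1 <- mask_size - margin - 1L
  mean_img <- cpp_window_mean_masked(px, choroid$valid_mask,
                                     r0, r1, r0, r1)
  mask <- interior_band_mask(choroid$valid_mask, margin) * choroid$valid_mask
  res <- (px - mean_img) * mask
  structure(list(pixels = res, valid_mask = mask, mask_size = mask_size),
            class = "corrected_choroid")
}

interior_band_mask <- function(valid, margin) {
  M <- nrow(valid); N <- ncol(valid)
  band <- matrix(0L, M, N)
  if (M > 2L * margin && N > 2L * margin)
    band[(margin + 1L):(M - margin), (margin + 1L):(N - margin)] <- 1L
  band
}

#' Validity mask of the corrected choroid
#'
#' The binary image marking pixels that take part in the morphological
#' analysis: valid (non-sentinel) choroid pixels restricted to the interior
#' band of [brightness_correction()].
#'
#' @param choroid a `"flattened_choroid"`.
#' @param mask_size averaging-mask side used for the band margin.
#' @return 0/1 integer matrix.
#' @export
build_mask <- function(choroid, mask_size = 30L) {
  stopifnot(inherits(choroid, "flattened_choroid"))
  margin <- mask_size %/% 2L
  interior_band_mask(choroid$valid_mask, margin) * choroid$valid_mask
}

#' Disc structuring element
#'
#' Discrete disc footprint of diameter `size` (odd): all offsets
#' `(dm, dn)` with `dm^2 + dn^2 <= r^2`, `r = (size - 1)/2`. Symmetric
#' about its centre and contained in a `size` x `size` bounding box.
#'
#' @param size odd diameter, >= 3 (the filter bank uses 3, 5, 7, 9, 11).
#' @return integer matrix with two columns (`dm`, `dn`), class
#'   `"structuring_element"`, attribute `size`.
#' @export
disc_se <- function(size) {
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L) stop("SE size must be odd and >= 3")
  r <- (size - 1L) / 2
  g <- expand.grid(dm = -r:r, dn = -r:r)
  g <- g[g$dm^2 + g$dn^2 <= r^2, , drop = FALSE]
  off <- as.matrix(g)
  dimnames(off) <- list(NULL, c("dm", "dn"))
  structure(off, size = size, class = c("structuring_element", "matrix"))
}

se_offsets <- function(se) {
  if (inherits(se, "structuring_element")) {
    matrix(as.integer(se), nrow = nrow(se), ncol = 2L)
  } else if (is.numeric(se) && length(se) == 1L) {
    se_offsets(disc_se(se))
  } else if (is.matrix(se) && ncol(se) == 2L) {
    matrix(as.integer(se), nrow = nrow(se), ncol = 2L)
  } else stop("se must be a size, a structuring_element, or an offset matrix")
}

# min-max normalization to [0,1]; a constant image maps to all zeros
normalize01 <- function(x, subset = NULL) {
  v <- if (is.null(subset)) x else x[subset]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(array(0, dim(x)))
  out <- (x - lo) / (hi - lo)
  pmin(pmax(out, 0), 1)
}

#' Multiscale morphological filter bank
#'
#' For each structuring-element size, applies the grey-scale composite
#' `min_SE(max_SE(corrected * mask))` — the neighborhood maximum followed by
#' the neighborhood minimum over a disc footprint, exactly in that order
#' (`order = "as-printed"`). The alternative `order = "opening"` applies the
#' minimum first. Since the vessels of interest are dark (negative
#' residuals), max-then-min removes dark structures smaller than the disc
#' while preserving larger ones, so the per-scale results encode the
#' object-size distribution. Window members falling outside the image are
#' ignored (shrinking window).
#'
#' @param corrected a `"corrected_choroid"` (or plain numeric matrix).
#' @param mask 0/1 matrix; defaults to the corrected mask (or all ones).
#' @param scales integer vector of odd SE sizes, default `c(3,5,7,9,11)`.
#' @param order `"as-printed"` (max then min, default) or `"opening"`.
#' @return named list of filtered matrices, one per scale.
#' @export
filter_bank <- function(corrected, mask = NULL,
                        scales = c(3L, 5L, 7L, 9L, 11L),
                        order = c("as-printed", "opening")) {
  order <- match.arg(order)
  if (inherits(corrected, "corrected_choroid")) {
    mask <- mask %||% corrected$valid_mask
    corrected <- corrected$pixels
  }
  if (length(scales) == 0L) stop("empty scale set")
  if (any(scales %% 2L == 0L | scales < 3L)) stop("scales must be odd and >= 3")
  mask <- mask %||% matrix(1L, nrow(corrected), ncol(corrected))
  src <- corrected * mask
  out <- lapply(scales, function(s) {
    off <- se_offsets(s)
    if (order == "as-printed") {
      cpp_neigh_extreme(cpp_neigh_extreme(src, off, TRUE, TRUE), off, FALSE, TRUE)
    } else {
      cpp_neigh_extreme(cpp_neigh_extreme(src, off, FALSE, TRUE), off, TRUE, TRUE)
    }
  })
  names(out) <- as.character(scales)
  out
}

#' Binarization of a filtered scale image
#'
#' Min-max normalizes the image over the masked region to `[0, 1]` and
#' marks pixels whose normalized value falls below `p_r` (dark objects =
#' choroidal vessels). A constant masked region is degenerate and yields an
#' all-zero output with a warning. Masked-out pixels are always 0.
#'
#' @param filtered numeric matrix (one filter-bank scale).
#' @param mask 0/1 matrix (default: all ones).
#' @param p_r threshold in (0, 1), default 0.5.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(filtered, mask = NULL, p_r = 0.5) {
  if (p_r <= 0 || p_r >= 1) stop("p_r must lie in (0, 1)")
  mask <- mask %||% matrix(1L, nrow(filtered), ncol(filtered))
  sel <- mask == 1L
  if (!any(sel)) return(matrix(0L, nrow(filtered), ncol(filtered)))
  v <- filtered[sel]
  if (max(v) <= min(v)) {
    warning("degenerate normalization (constant masked region); all-zero output")
    return(matrix(0L, nrow(filtered), ncol(filtered)))
  }
  norm <- (filtered - min(v)) / (max(v) - min(v))
  out <- matrix(0L, nrow(filtered), ncol(filtered))
  out[sel & norm < p_r] <- 1L
  out
}

#' Parameters of the conditional morphological operators
#'
#' @param p_we erosion effectiveness in `[-1, 1]`. `(1 - p_we)` scales the
#'   erosion condition: at `p_we = 1` erosion never fires (identity); at
#'   `p_we = 0` intensity is maximal.
#' @param p_wd dilation effectiveness in `[-1, 1]`, acting through
#'   `(p_wd + 1)` symmetrically.
#' @param p_mn condition threshold in `[0, 1]`; a scalar (constant map, the
#'   usual case) or a full matrix.
#' @param n_rounds number of sequential dilation+erosion rounds (default 3).
#' @return an object of class `"conditional_params"`.
#' @export
conditional_params <- function(p_we = 0, p_wd = 0, p_mn = 0.5, n_rounds = 3L) {
  if (p_we < -1 || p_we > 1) stop("p_we must lie in [-1, 1]")
  if (p_wd < -1 || p_wd > 1) stop("p_wd must lie in [-1, 1]")
  if (any(p_mn < 0) || any(p_mn > 1)) stop("p_mn must lie in [0, 1]")
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  structure(list(p_we = p_we, p_wd = p_wd, p_mn = p_mn,
                 n_rounds = as.integer(n_rounds)),
            class = "conditional_params")
}

#' The effectiveness-constant grid for parameter sweeps
#'
#' @return numeric vector `-1.0, -0.9, ..., 1.0`.
#' @export
effectiveness_grid <- function() round(seq(-1, 1, by = 0.1), 10)

cond_prep <- function(binary, grey, params) {
  if (!all(dim(binary) == dim(grey))) stop("binary and grey images must share shape")
  if (!inherits(params, "conditional_params")) params <- do.call(conditional_params, params)
  p_mn <- params$p_mn
  if (length(p_mn) == 1L) p_mn <- matrix(p_mn, nrow(binary), ncol(binary))
  if (!all(dim(p_mn) == dim(binary))) stop("p_mn map must match the image shape")
  list(params = params, p_mn = p_mn, grey01 = normalize01(grey))
}

#' Conditional erosion of a binary scale image
#'
#' Per pixel: where `(1 - p_we) * p_mn <= s_re` the input is kept; elsewhere
#' the pixel becomes the minimum of the binary image over the structuring
#' element placed with forward offsets. `s_re` is the mean of the grey scale
#' image (min-max normalized to `[0, 1]`, making it commensurate with the
#' left-hand side) over the same forward-offset window. Out-of-image window
#' members are ignored.
#'
#' @param binary 0/1 matrix (a binarized scale image).
#' @param grey numeric matrix (the corresponding filtered scale image).
#' @param params a [conditional_params()].
#' @param se SE size, [disc_se()] object, or offset matrix.
#' @return 0/1 integer matrix.
#' @export
conditional_erosion <- function(binary, grey, params = conditional_params(),
                                se = 3L) {
  pr <- cond_prep(binary, grey, params)
  off <- se_offsets(se)
  s_re <- cpp_neigh_mean(pr$grey01, off, TRUE)
  keep <- (1 - pr$params$p_we) * pr$p_mn <= s_re
  eroded <- cpp_neigh_extreme(binary * 1.0, off, FALSE, TRUE)
  out <- ifelse(keep, binary, eroded)
  matrix(as.integer(out), nrow(binary), ncol(binary))
}

#' Conditional dilation of a binary scale image
#'
#' Per pixel: where `(p_wd + 1) * p_mn >= s_rd` the input is kept; elsewhere
#' the pixel becomes the maximum of the binary image over the structuring
#' element placed with backward offsets. `s_rd` is the mean of the
#' normalized grey image over the same backward-offset window.
#'
#' @inheritParams conditional_erosion
#' @return 0/1 integer matrix.
#' @export
conditional_dilation <- function(binary, grey, params = conditional_params(),
                                 se = 3L) {
  pr <- cond_prep(binary, grey, params)
  off <- se_offsets(se)
  s_rd <- cpp_neigh_mean(pr$grey01, off, FALSE)
  keep <- (pr$params$p_wd + 1) * pr$p_mn >= s_rd
  dilated <- cpp_neigh_extreme(binary * 1.0, off, TRUE, FALSE)
  out <- ifelse(keep, binary, dilated)
  matrix(as.integer(out), nrow(binary), ncol(binary))
}

#' Conditional refinement of a binarized scale image
#'
#' Sequentially applies conditional dilation then conditional erosion,
#' `n_rounds` times (default 3), removing small artefacts and closing holes
#' in vessel objects. When a validity mask is supplied, pixels outside it
#' are reset to 0 after every operation, so the refinement can never grow
#' objects into the excluded region.
#'
#' @inheritParams conditional_erosion
#' @param mask optional 0/1 validity matrix.
#' @return 0/1 integer matrix.
#' @export
refine <- function(binary, grey, params = conditional_params(), se = 3L,
                   mask = NULL) {
  if (!inherits(params, "conditional_params")) params <- do.call(conditional_params, params)
  out <- binary
  for (r in seq_len(params$n_rounds)) {
    out <- conditional_dilation(out, grey, params, se)
    if (!is.null(mask)) out <- out * mask
    out <- conditional_erosion(out, grey, params, se)
    if (!is.null(mask)) out <- out * mask
  }
  matrix(as.integer(out), nrow(binary), ncol(binary))
}

#' Full multiscale morphological stack for one corrected choroid
#'
#' Runs the filter bank, binarization and conditional refinement at every
#' scale, producing per scale the filtered image `L_O`, the binary image
#' `L_B` and the refined binary image `L_K`.
#'
#' @param corrected a `"corrected_choroid"`.
#' @param scales odd SE sizes (default `c(3,5,7,9,11)`).
#' @param params a [conditional_params()].
#' @param p_r_bin binarization threshold (default 0.5).
#' @param order filter-bank order flag, see [filter_bank()].
#' @return an object of class `"scale_stack"`: named list (one entry per
#'   scale) of lists with `L_O`, `L_B`, `L_K`.
#' @export
scale_stack <- function(corrected, scales = c(3L, 5L, 7L, 9L, 11L),
                        params = conditional_params(), p_r_bin = 0.5,
                        order = c("as-printed", "opening")) {
  stopifnot(inherits(corrected, "corrected_choroid"))
  order <- match.arg(order)
  mask <- corrected$valid_mask
  bank <- filter_bank(corrected, mask, scales, order)
  out <- lapply(names(bank), function(s) {
    L_O <- bank[[s]]
    L_B <- binarize(L_O, mask, p_r_bin)
    L_K <- refine(L_B, L_O, params, as.integer(s), mask)
    list(L_O = L_O, L_B = L_B, L_K = L_K)
  })
  names(out) <- names(bank)
  structure(out, scales = as.integer(names(bank)), class = "scale_stack")
}

#' Persist a scale stack as per-scale PNGs with a JSON sidecar
#'
#' Writes, for every scale, the binary images `L_B` and `L_K` as 0/255 PNG
#' and the filtered image `L_O` min-max scaled to 8 bits, plus a
#' `stack.json` sidecar recording the scales, the conditional parameters
#' and the original `L_O` value ranges (so the scaling is invertible to
#' 8-bit precision).
#'
#' @param stack a `"scale_stack"`.
#' @param dir output directory (created if missing).
#' @param params the [conditional_params()] the stack was built with
#'   (recorded in the sidecar).
#' @return invisibly, the sidecar list.
#' @export
write_scale_stack <- function(stack, dir, params = conditional_params()) {
  stopifnot(inherits(stack, "scale_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- attr(stack, "scales")
  ranges <- lapply(stack, function(sc) range(sc$L_O))
  for (i in seq_along(scales)) {
    s <- scales[i]
    sc <- stack[[i]]
    rg <- ranges[[i]]
    lo8 <- if (rg[2] > rg[1]) {
      round(255 * (sc$L_O - rg[1]) / (rg[2] - rg[1]))
    } else sc$L_O * 0
    write_bscan(matrix(as.integer(lo8), nrow(sc$L_O)),
                file.path(dir, sprintf("L_O_%02d.png", s)))
    write_bscan(sc$L_B * 255L, file.path(dir, sprintf("L_B_%02d.png", s)))
    write_bscan(sc$L_K * 255L, file.path(dir, sprintf("L_K_%02d.png", s)))
  }
  sidecar <- list(scales = scales,
                  p_we = params$p_we, p_wd = params$p_wd,
                  p_mn = if (length(params$p_mn) == 1L) params$p_mn else "map",
                  n_rounds = params$n_rounds,
                  L_O_ranges = setNames(ranges, as.character(scales)))
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @export
print.scale_stack <- function(x, ...) {
  cat(sprintf("<scale_stack> scales %s, %d x %d\n",
              paste(attr(x, "scales"), collapse = ","),
              nrow(x[[1]]$L_O), ncol(x[[1]]$L_O)))
  invisible(x)
}
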
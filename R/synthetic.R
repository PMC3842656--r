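#' Specification of a synthetic OCT B-scan phantom
#'
#' Builds the parameter object consumed by [generate_bscan()]. The phantom
#' emulates the qualitative structure of a fundus OCT B-scan: a moderately
#' reflective retina on top, a bright and smoothly curved RPE band, and a
#' darker choroid below it containing dark elliptical vessel cross-sections.
#' Class-conditional structure follows the three choroidal imaging types:
#'
#' * `"Z1"` — vertical shadow bands attenuate the choroid under simulated
#'   retinal lesions (`shadow_band_spec`);
#' * `"Z2"` — all sub-RPE intensities are multiplied by
#'   `global_dimming_factor` (global brightness reduction);
#' * `"Z3"` — vessels share a single brightness and a narrow depth band and
#'   the choroidal texture noise is reduced (uniform image);
#' * `"none"` — no class effect (plumbing/diagnostic use).
#'
#' Vessels are dark on a brighter choroid because the downstream
#' binarization selects low-intensity pixels. The RPE band is generated
#' top-heavy (its first two rows carry the full `rpe_brightness`, the rest
#' fade towards the choroid level) so that the per-column brightness cluster
#' has a well-defined top edge; the true contour refers to the first band
#' row.
#'
#' @param class_label one of `"Z1"`, `"Z2"`, `"Z3"`, `"none"`.
#' @param height,width image size in pixels (rows, columns). The default
#'   matches the 256 x 1024 acquisition geometry of the scans the method was
#'   designed for; resolution is configurable and does not change the
#'   analysis.
#' @param rpe_curve_coeffs polynomial coefficients (intercept first) of the
#'   true RPE row evaluated on the normalized column coordinate
#'   `t = (n-1)/(N-1)` in `[0,1]`.
#' @param rpe_brightness grey level of the RPE band top (0-255).
#' @param rpe_thickness RPE band thickness in pixels (>= 2).
#' @param retina_brightness grey level of the retina above the RPE.
#' @param choroid_base_brightness grey level of the choroid stroma.
#' @param vessel_count number of vessel cross-sections.
#' @param vessel_radius_range two integers, min/max semi-axis in pixels;
#'   vessel bounding boxes must stay within 20 x 20 pixels (semi-axes <= 9),
#'   the maximum object size the filter bank is dimensioned for.
#' @param vessel_brightness_range two grey levels, per-vessel brightness
#'   drawn uniformly (ignored for `"Z3"`, see `vessel_brightness_uniform`).
#' @param vessel_brightness_uniform single grey level used for every vessel
#'   of a `"Z3"` phantom.
#' @param shadow_band_spec `NULL` or a data frame with columns `centre`,
#'   `width`, `attenuation` describing vertical sub-RPE shadow bands; for
#'   `"Z1"` with `NULL`, `n_shadow_bands` bands are drawn at random columns.
#' @param n_shadow_bands,shadow_band_width,shadow_attenuation defaults used
#'   when `"Z1"` bands are drawn automatically.
#' @param global_dimming_factor multiplier in (0, 1] applied to all sub-RPE
#'   intensities (`"Z2"` uses the default 0.6; other classes 1).
#' @param texture_sd standard deviation of the Gaussian texture noise added
#'   to the sub-RPE region; `"Z3"` uses `texture_sd_uniform`.
#' @param texture_sd_uniform reduced texture noise for `"Z3"`.
#' @param z3_depth_frac,z3_depth_jitter `"Z3"` vessel placement: fixed
#'   fraction of the local choroid depth, plus a small Gaussian jitter (rows).
#' @param sp_noise_density fraction of pixels replaced by salt-and-pepper
#'   noise (half 0, half 255), applied last.
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   image.
#'
#' @return an object of class `"phantom_spec"` (a validated list).
#' @seealso [generate_bscan()], [generate_dataset()]
#' @export
phantom_spec <- function(class_label = c("Z1", "Z2", "Z3", "none"),
                         height = 256L, width = 1024L,
                         rpe_curve_coeffs = c(60, 30, -25),
                         rpe_brightness = 230,
                         rpe_thickness = 4L,
                         retina_brightness = 90,
                         choroid_base_brightness = 140,
                         vessel_count = 25L,
                         vessel_radius_range = c(3L, 9L),
                         vessel_brightness_range = c(40, 90),
                         vessel_brightness_uniform = 60,
                         shadow_band_spec = NULL,
                         n_shadow_bands = 3L,
                         shadow_band_width = 80,
                         shadow_attenuation = 0.55,
                         global_dimming_factor = NULL,
                         texture_sd = 8,
                         texture_sd_uniform = 2,
                         z3_depth_frac = 0.3,
                         z3_depth_jitter = 2,
                         sp_noise_density = 0.02,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  if (is.null(global_dimming_factor)) {
    global_dimming_factor <- if (class_label == "Z2") 0.6 else 1.0
  }
  spec <- list(
    class_label = class_label,
    height = as.integer(height), width = as.integer(width),
    rpe_curve_coeffs = as.numeric(rpe_curve_coeffs),
    rpe_brightness = rpe_brightness,
    rpe_thickness = as.integer(rpe_thickness),
    retina_brightness = retina_brightness,
    choroid_base_brightness = choroid_base_brightness,
    vessel_count = as.integer(vessel_count),
    vessel_radius_range = as.integer(vessel_radius_range),
    vessel_brightness_range = as.numeric(vessel_brightness_range),
    vessel_brightness_uniform = vessel_brightness_uniform,
    shadow_band_spec = shadow_band_spec,
    n_shadow_bands = as.integer(n_shadow_bands),
    shadow_band_width = shadow_band_width,
    shadow_attenuation = shadow_attenuation,
    global_dimming_factor = global_dimming_factor,
    texture_sd = if (class_label == "Z3") texture_sd_uniform else texture_sd,
    z3_depth_frac = z3_depth_frac,
    z3_depth_jitter = z3_depth_jitter,
    sp_noise_density = sp_noise_density,
    seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$height >= 16L, spec$width >= 16L,
            spec$rpe_thickness >= 2L,
            spec$vessel_count >= 0L)
  if (any(spec$vessel_radius_range <= 0L))
    stop("vessel radii must be positive")
  if (any(spec$vessel_radius_range > 9L))
    stop("vessel semi-axes above 9 px exceed the 20x20 px object bound")
  if (spec$sp_noise_density < 0 || spec$sp_noise_density >= 1)
    stop("sp_noise_density must lie in [0, 1)")
  if (spec$global_dimming_factor <= 0 || spec$global_dimming_factor > 1)
    stop("global_dimming_factor must lie in (0, 1]")
  y <- true_contour(spec)
  if (any(y < 1L) || any(y + spec$rpe_thickness - 1L > spec$height))
    stop("RPE curve places the band outside the image; adjust ",
         "rpe_curve_coeffs / rpe_thickness / height")
  invisible(spec)
}

#' True RPE contour of a phantom specification
#'
#' Evaluates the RPE-curve polynomial of a [phantom_spec()] at every column,
#' rounded to integer row indices (1-based, row of the band top).
#'
#' @param spec a `"phantom_spec"`.
#' @return integer vector of length `width`.
#' @export
true_contour <- function(spec) {
  t <- if (spec$width > 1L) (seq_len(spec$width) - 1) / (spec$width - 1) else 0
  y <- rep(0, spec$width)
  for (k in seq_along(spec$rpe_curve_coeffs)) {
    y <- y + spec$rpe_curve_coeffs[k] * t^(k - 1)
  }
  as.integer(round(y))
}

# Run expr with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic OCT B-scan with known ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: retina, top-heavy RPE
#' band along the true contour, choroid with dark elliptical vessels,
#' class-conditional structure (shadow bands for `Z1`, global sub-RPE dimming
#' for `Z2`, uniform vessels and reduced texture noise for `Z3`), Gaussian
#' texture noise, and finally salt-and-pepper noise (independent per-pixel
#' replacement by 0 or 255, each with probability `sp_noise_density / 2`).
#'
#' @param spec a `"phantom_spec"`.
#' @return an object of class `"oct_phantom"`: a list with elements
#'   `image` (integer matrix, grey levels 0-255), `contour` (integer vector,
#'   true RPE row per column), `vessels` (data frame of vessel centres,
#'   semi-axes and brightnesses), and `spec`.
#' @export
generate_bscan <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  with_seed(spec$seed, generate_bscan_impl(spec))
}

generate_bscan_impl <- function(spec) {
  M <- spec$height; N <- spec$width
  y <- true_contour(spec)
  Tk <- spec$rpe_thickness
  img <- matrix(spec$retina_brightness, M, N)

  # RPE band: two full-brightness rows, then a linear fade to the choroid
  nb <- min(2L, Tk)
  fade <- if (Tk > nb) {
    seq(spec$rpe_brightness, spec$choroid_base_brightness,
        length.out = Tk - nb + 1L)[-1L]
  } else numeric(0)
  profile <- c(rep(spec$rpe_brightness, nb), fade)
  rows <- matrix(seq_len(M), M, N)
  ycols <- matrix(y, M, N, byrow = TRUE)
  below <- rows >= ycols + Tk
  img[below] <- spec$choroid_base_brightness
  for (k in seq_len(Tk)) {
    img[rows == ycols + k - 1L] <- profile[k]
  }

  # vessels: dark ellipses fully below the band
  nv <- spec$vessel_count
  vessels <- data.frame(cx = integer(0), cy = integer(0),
                        rx = integer(0), ry = integer(0),
                        brightness = numeric(0))
  if (nv > 0L) {
    rr <- spec$vessel_radius_range
    rx <- sample(seq(rr[1], rr[2]), nv, replace = TRUE)
    ry <- sample(seq(rr[1], rr[2]), nv, replace = TRUE)
    cx <- pmin(pmax(round(runif(nv, 1 + rr[2], N - rr[2])), 1L + rx), N - rx)
    cy <- integer(nv)
    bright <- if (spec$class_label == "Z3") {
      rep(spec$vessel_brightness_uniform, nv)
    } else {
      runif(nv, spec$vessel_brightness_range[1], spec$vessel_brightness_range[2])
    }
    for (v in seq_len(nv)) {
      top <- y[cx[v]] + Tk + 3L + ry[v]
      bot <- M - 3L - ry[v]
      if (top >= bot) { cy[v] <- NA_integer_; next }
      if (spec$class_label == "Z3") {
        depth <- M - (y[cx[v]] + Tk)
        c0 <- y[cx[v]] + Tk + round(spec$z3_depth_frac * depth) +
          round(rnorm(1, 0, spec$z3_depth_jitter))
        cy[v] <- min(max(c0, top), bot)
      } else {
        cy[v] <- round(runif(1, top, bot))
      }
      mrng <- max(1L, cy[v] - ry[v]):min(M, cy[v] + ry[v])
      nrng <- max(1L, cx[v] - rx[v]):min(N, cx[v] + rx[v])
      for (n in nrng) {
        dm <- (mrng - cy[v]) / ry[v]
        dn <- (n - cx[v]) / rx[v]
        inside <- dm * dm + dn * dn <= 1
        mm <- mrng[inside & (mrng >= y[n] + Tk)]
        img[mm, n] <- bright[v]
      }
    }
    vessels <- data.frame(cx = cx, cy = cy, rx = rx, ry = ry,
                          brightness = bright)
  }

  # texture noise in the sub-RPE region
  if (spec$texture_sd > 0) {
    noise <- matrix(rnorm(M * N, 0, spec$texture_sd), M, N)
    img[below] <- img[below] + noise[below]
  }

  # class effects on the sub-RPE region
  if (spec$class_label == "Z1") {
    bands <- spec$shadow_band_spec
    if (is.null(bands)) {
      nbd <- spec$n_shadow_bands
      bands <- data.frame(
        centre = round(runif(nbd, 1, N)),
        width = pmax(10, round(rnorm(nbd, spec$shadow_band_width,
                                     spec$shadow_band_width / 8))),
        attenuation = rep(spec$shadow_attenuation, nbd))
    }
    for (b in seq_len(nrow(bands))) {
      half <- bands$width[b] / 2
      cols <- which(abs(seq_len(N) - bands$centre[b]) <= half)
      if (length(cols) == 0L) next
      sel <- below[, cols, drop = FALSE]
      img[, cols][sel] <- img[, cols][sel] * bands$attenuation[b]
    }
    attr(vessels, "shadow_bands") <- bands
  }
  if (spec$global_dimming_factor < 1) {
    img[below] <- img[below] * spec$global_dimming_factor
  }

  img <- round(pmin(pmax(img, 0), 255))

  # salt-and-pepper noise last
  if (spec$sp_noise_density > 0) {
    hit <- runif(M * N) < spec$sp_noise_density
    if (any(hit)) {
      img[hit] <- ifelse(runif(sum(hit)) < 0.5, 0, 255)
    }
  }

  structure(list(image = matrix(as.integer(img), M, N),
                 contour = y, vessels = vessels, spec = spec),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("<oct_phantom> %d x %d, class %s, %d vessels, seed %d\n",
              nrow(x$image), ncol(x$image), x$spec$class_label,
              nrow(x$vessels), x$spec$seed))
  invisible(x)
}

#' Generate a labelled synthetic dataset with a stratified split
#'
#' Draws `n_per_class` phantoms for each of the three imaging types and
#' assigns each image to the learning / validation / test split, stratified
#' by class, with split sizes matching the requested proportions to within
#' one image (largest-remainder rounding). Per-image seeds are derived from
#' `seed`, so the whole dataset is reproducible.
#'
#' @param n_per_class images per class (>= 5).
#' @param split named or unnamed numeric vector of three proportions
#'   (learning, validation, test) summing to 1. Default `c(0.6, 0.2, 0.2)`.
#' @param seed integer master seed.
#' @param ... further arguments passed to [phantom_spec()] (for example
#'   `height`, `width`).
#' @return an object of class `"oct_dataset"`: list with `images` (list of
#'   `"oct_phantom"`), `labels` (factor Z1/Z2/Z3), `split` (factor
#'   learning/validation/test), `seed`.
#' @export
generate_dataset <- function(n_per_class, split = c(0.6, 0.2, 0.2),
                             seed = 1L, ...) {
  if (n_per_class < 5L) stop("n_per_class must be at least 5")
  split <- as.numeric(split)
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-8)
    stop("split must be three proportions summing to 1")
  classes <- c("Z1", "Z2", "Z3")
  split_names <- c("learning", "validation", "test")

  with_seed(seed, {
    img_seeds <- sample.int(.Machine$integer.max - 1L,
                            3L * n_per_class)
    images <- vector("list", 3L * n_per_class)
    labels <- character(3L * n_per_class)
    splits <- character(3L * n_per_class)
    idx <- 0L
    for (cl in classes) {
      counts <- largest_remainder(n_per_class, split)
      assign_vec <- sample(rep(split_names, counts))
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1L
        sp <- phantom_spec(class_label = cl, seed = img_seeds[idx], ...)
        images[[idx]] <- generate_bscan(sp)
        labels[idx] <- cl
        splits[idx] <- assign_vec[i]
      }
    }
    structure(list(images = images,
                   labels = factor(labels, levels = classes),
                   split = factor(splits, levels = split_names),
                   seed = as.integer(seed)),
              class = "oct_dataset")
  })
}

largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' @export
print.oct_dataset <- function(x, ...) {
  cat(sprintf("<oct_dataset> %d images (%s), split %s\n",
              length(x$images),
              paste(table(x$labels), collapse = "/"),
              paste(table(x$split), collapse = "/")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as an 8-bit grey PNG, its true contour as a one-row-per
#' -column CSV, and a sidecar manifest (`manifest.csv`) with columns
#' `filename`, `class_label`, `split`, `seed`, `contour_file`.
#'
#' @param dataset an `"oct_dataset"`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "oct_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$images)
  manifest <- data.frame(
    filename = sprintf("bscan_%04d.png", seq_len(n)),
    class_label = as.character(dataset$labels),
    split = as.character(dataset$split),
    seed = vapply(dataset$images, function(p) p$spec$seed, integer(1)),
    contour_file = sprintf("bscan_%04d_contour.csv", seq_len(n)),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    write_bscan(dataset$images[[i]]$image, file.path(dir, manifest$filename[i]))
    write_contour(dataset$images[[i]]$contour,
                  file.path(dir, manifest$contour_file[i]))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
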
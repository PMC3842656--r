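#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain in one validated
#' object. The two distinct roles of the threshold symbol shared by RPE
#' detection and binarization are kept as separate named parameters
#' (`p_r_rpe`, `p_r_bin`).
#'
#' @param rows,cols image geometry for RAW input (default 256 x 1024).
#' @param median_mask odd side of the median prefilter mask (default 3).
#' @param p_r_rpe RPE bright-cluster threshold coefficient in (0, 1]
#'   (default 0.9).
#' @param mean_mask side of the brightness-correction averaging mask
#'   (default 30; at least twice the 20-pixel maximum object size).
#' @param p_r_bin binarization threshold in (0, 1) (default 0.5).
#' @param scales structuring-element sizes of the filter bank.
#' @param p_we,p_wd conditional-operator effectiveness constants in
#'   `[-1, 1]` (default 0 = maximal intensity).
#' @param p_mn conditional-operator threshold in `[0, 1]` (default 0.5).
#' @param n_rounds conditional refinement rounds (default 3).
#' @param morphology_order `"as-printed"` (max then min) or `"opening"`.
#' @param k_folds pruning cross-validation folds (default 10).
#' @param seed master seed for all randomness.
#' @param feature_pool column indices enumerated by [subset_search()]
#'   in desk-scale runs.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(rows = 256L, cols = 1024L,
                            median_mask = 3L,
                            p_r_rpe = 0.9,
                            mean_mask = 30L,
                            p_r_bin = 0.5,
                            scales = c(3L, 5L, 7L, 9L, 11L),
                            p_we = 0, p_wd = 0, p_mn = 0.5,
                            n_rounds = 3L,
                            morphology_order = c("as-printed", "opening"),
                            k_folds = 10L,
                            seed = 1L,
                            feature_pool = 1:8) {
  morphology_order <- match.arg(morphology_order)
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              median_mask = as.integer(median_mask),
              p_r_rpe = p_r_rpe, mean_mask = as.integer(mean_mask),
              p_r_bin = p_r_bin, scales = as.integer(scales),
              p_we = p_we, p_wd = p_wd, p_mn = p_mn,
              n_rounds = as.integer(n_rounds),
              morphology_order = morphology_order,
              k_folds = as.integer(k_folds), seed = as.integer(seed),
              feature_pool = as.integer(feature_pool))
  if (cfg$median_mask %% 2L == 0L) stop("median_mask must be odd")
  if (cfg$p_r_rpe <= 0 || cfg$p_r_rpe > 1) stop("p_r_rpe must lie in (0, 1]")
  if (cfg$p_r_bin <= 0 || cfg$p_r_bin >= 1) stop("p_r_bin must lie in (0, 1)")
  if (any(cfg$scales %% 2L == 0L) || any(cfg$scales < 3L))
    stop("scales must be odd and >= 3")
  conditional_params(cfg$p_we, cfg$p_wd, cfg$p_mn, cfg$n_rounds)  # validates
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %-16s %s\n", "hash", config_hash(x)))
  invisible(x)
}

#' Write / read a pipeline configuration (YAML)
#'
#' The file round-trips losslessly through [pipeline_config()] validation.
#'
#' @param config a `"pipeline_config"`.
#' @param path YAML file.
#' @return `write_config`: invisibly `path`; `read_config`: a validated
#'   `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Short content hash of a configuration
#'
#' FNV-1a over the canonical YAML text; embedded in pipeline output files
#' so results can be traced to the configuration that produced them.
#'
#' @param config a `"pipeline_config"`.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Process one B-scan through preprocessing, morphology and features
#'
#' @param image integer matrix of grey levels 0-255.
#' @param config a [pipeline_config()].
#' @return list with `features` (named length-20 vector), `contour`,
#'   `choroid` (`"flattened_choroid"`), `corrected`
#'   (`"corrected_choroid"`) and `stack` (`"scale_stack"`).
#' @export
process_bscan <- function(image, config = pipeline_config()) {
  choroid <- preprocess_bscan(image, config)
  corrected <- brightness_correction(choroid, config$mean_mask)
  params <- conditional_params(config$p_we, config$p_wd, config$p_mn,
                               config$n_rounds)
  stack <- scale_stack(corrected, config$scales, params, config$p_r_bin,
                       config$morphology_order)
  list(features = extract_features(stack, corrected),
       contour = choroid$contour, choroid = choroid,
       corrected = corrected, stack = stack)
}

#' Run the full pipeline over a set of B-scans
#'
#' Accepts an `"oct_dataset"`, a list of images/phantoms, or a character
#' vector of image paths. Each scan goes through preprocessing, morphology
#' and feature extraction; failures are recorded per image and the pipeline
#' continues with the rest. Optionally applies a trained model to emit
#' predicted labels.
#'
#' @param input `"oct_dataset"`, list of matrices / `"oct_phantom"`s, or
#'   file paths.
#' @param config a [pipeline_config()].
#' @param model optional `"choroid_cart"` (or JSON model from
#'   [read_model()]) used to add a `predicted` column.
#' @param out_csv optional path; when given, the feature table is written
#'   there.
#' @return data frame with `image_id`, optional `class_label` and `split`,
#'   `w1` ... `w20`, `config_hash`, optional `predicted`; failed images are
#'   listed in attribute `"failures"` (named character vector of error
#'   messages).
#' @export
run_pipeline <- function(input, config = pipeline_config(), model = NULL,
                         out_csv = NULL) {
  items <- pipeline_items(input, config)
  rows <- list(); failures <- character(0)
  for (i in seq_along(items$images)) {
    id <- items$ids[i]
    res <- tryCatch(process_bscan(items$images[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      next
    }
    row <- data.frame(image_id = id, stringsAsFactors = FALSE)
    if (!is.null(items$labels)) row$class_label <- items$labels[i]
    if (!is.null(items$split)) row$split <- items$split[i]
    row <- cbind(row, as.data.frame(as.list(res$features)))
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(0))
  if (nrow(out) > 0) out$config_hash <- config_hash(config)
  if (!is.null(model) && nrow(out) > 0) {
    out$predicted <- as.character(predict(model, out[, feature_names()]))
  }
  attr(out, "failures") <- failures
  if (!is.null(out_csv)) write_features(out, out_csv)
  out
}

pipeline_items <- function(input, config) {
  if (inherits(input, "oct_dataset")) {
    list(images = lapply(input$images, `[[`, "image"),
         ids = sprintf("bscan_%04d", seq_along(input$images)),
         labels = as.character(input$labels),
         split = as.character(input$split))
  } else if (is.character(input)) {
    list(images = lapply(input, read_bscan, rows = config$rows,
                         cols = config$cols),
         ids = basename(input), labels = NULL, split = NULL)
  } else if (is.list(input)) {
    imgs <- lapply(input, function(x) {
      if (inherits(x, "oct_phantom")) x$image else x
    })
    list(images = imgs, ids = sprintf("bscan_%04d", seq_along(imgs)),
         labels = NULL, split = NULL)
  } else if (is.matrix(input)) {
    list(images = list(input), ids = "bscan_0001", labels = NULL,
         split = NULL)
  } else stop("unsupported input type")
}

#' Feature table of a labelled dataset
#'
#' Convenience wrapper: runs [run_pipeline()] on an `"oct_dataset"` and
#' returns the feature table with labels and split columns, erroring if any
#' image failed.
#'
#' @param dataset an `"oct_dataset"`.
#' @param config a [pipeline_config()].
#' @return data frame, see [run_pipeline()].
#' @export
dataset_features <- function(dataset, config = pipeline_config()) {
  out <- run_pipeline(dataset, config)
  fails <- attr(out, "failures")
  if (length(fails) > 0)
    stop("pipeline failures: ", paste(names(fails), collapse = ", "))
  out
}
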
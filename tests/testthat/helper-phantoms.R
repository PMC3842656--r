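# Small phantom geometry shared across tests: full acquisition geometry is
# not needed to exercise the math, and 96 x 192 keeps the suite quick.
small_spec <- function(class_label = "none", seed = 1L, ...) {
  args <- list(class_label = class_label, seed = seed,
               height = 96L, width = 192L,
               rpe_curve_coeffs = c(30, 10, -8),
               vessel_count = 8L, ...)
  do.call(phantom_spec, args)
}

# the geometry used for recovery / end-to-end checks (denser content)
study_spec <- function(class_label = "Z1", seed = 1L, ...) {
  phantom_spec(class_label = class_label, seed = seed,
               height = 144L, width = 512L, ...)
}

study_config <- function(...) pipeline_config(rows = 144L, cols = 512L, ...)

# true sub-RPE (below the band) selector for a phantom
choroid_mask_from_truth <- function(ph) {
  M <- nrow(ph$image); N <- ncol(ph$image)
  rows <- matrix(seq_len(M), M, N)
  ytop <- matrix(ph$contour + ph$spec$rpe_thickness, M, N, byrow = TRUE)
  rows >= ytop
}

# hand-built flattened choroid from a plain matrix (fully valid)
as_flat <- function(px) {
  flatten_choroid(px, rep(1L, ncol(px)))
}

random_binary <- function(M, N, p = 0.4) {
  matrix(as.integer(runif(M * N) < p), M, N)
}

# the 100-per-class study dataset and its features, computed once per
# session and shared by the end-to-end checks
study_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(100, seed = 20260927, height = 144L,
                             width = 512L)
      cache <<- dataset_features(ds, study_config())
    }
    cache
  }
})
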
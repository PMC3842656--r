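test_that("brightness correction zeroes constants and matches the windowed-mean oracle", {
  const <- as_flat(matrix(120, 40, 40))
  corr <- brightness_correction(const)
  expect_true(all(corr$pixels[corr$valid_mask == 1] == 0))

  # single impulse of amplitude A on a constant background
  A <- 60
  imp <- matrix(100, 40, 40); imp[20, 20] <- 100 + A
  ci <- brightness_correction(as_flat(imp))
  expect_equal(ci$pixels[20, 20], A * (1 - 1 / 900))

  set.seed(41)
  rnd <- as_flat(matrix(runif(64 * 64, 0, 255), 64, 64))
  cr <- brightness_correction(rnd)
  expect_equal(cr$pixels, oracle_brightness_correction(rnd), tolerance = 1e-12)
  expect_error(brightness_correction(as_flat(matrix(0, 20, 20))), "smaller")
})

test_that("the validity mask is the valid choroid restricted to the interior band", {
  full <- as_flat(matrix(1, 40, 50))
  m <- build_mask(full)
  expect_identical(sum(m), (40L - 30L) * (50L - 30L))
  expect_true(all(m[1:15, ] == 0) && all(m[, 1:15] == 0))

  empty <- structure(list(pixels = matrix(-1, 40, 50),
                          valid_mask = matrix(0L, 40, 50)),
                     class = "flattened_choroid")
  expect_true(all(build_mask(empty) == 0))

  # area bookkeeping against the true contour
  ph <- generate_bscan(small_spec("Z3", seed = 17L, sp_noise_density = 0))
  fl <- flatten_choroid(build_rpe_image(ph$image, ph$contour), ph$contour)
  m2 <- build_mask(fl)
  M <- nrow(ph$image)
  depth <- M - ph$contour + 1L
  cols <- 16:(ncol(ph$image) - 15)
  expected <- sum(pmin(pmax(depth[cols] - 15L, 0L), M - 30L))
  expect_identical(sum(m2), expected)
})

test_that("disc structuring elements are symmetric and bounded", {
  for (s in c(3, 5, 7, 9, 11)) {
    off <- disc_se(s)
    expect_true(all(abs(off) <= (s - 1) / 2))
    # symmetric about the centre: offsets closed under negation
    keys <- paste(off[, 1], off[, 2])
    expect_setequal(keys, paste(-off[, 1], -off[, 2]))
  }
  expect_error(disc_se(4), "odd")
})

test_that("the filter bank is flat-invariant, fills pits, and matches the oracle", {
  const <- matrix(7, 12, 12)
  fb <- filter_bank(const, scales = 3)
  expect_true(all(fb[["3"]] == 7))

  pit <- matrix(10, 9, 9); pit[5, 5] <- 10 - 4
  fb2 <- filter_bank(pit, scales = 3)
  expect_identical(fb2[["3"]][5, 5], 10)

  set.seed(77)
  for (rep in 1:3) {
    img <- matrix(rnorm(144), 12, 12)
    for (s in c(3, 5, 7, 9, 11)) {
      off <- unclass(disc_se(s))
      for (ord in c("as-printed", "opening")) {
        got <- filter_bank(img, scales = s, order = ord)[[as.character(s)]]
        expect_equal(got, oracle_filter_bank_scale(img, off, ord),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(filter_bank(const, scales = integer(0)), "empty")
})

test_that("binarization selects the dark half of the normalized range", {
  two <- matrix(c(10, 200), 4, 4)
  b <- binarize(two)
  expect_identical(b, matrix(c(1L, 0L), 4, 4))

  expect_warning(bc <- binarize(matrix(5, 4, 4)), "degenerate")
  expect_true(all(bc == 0))

  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  br <- binarize(ramp)
  expect_identical(br == 1L, (ramp - 0) / 255 < 0.5)
  expect_error(binarize(two, p_r = 1), "0, 1")

  # masked-out pixels never 1
  mask <- matrix(0L, 4, 4); mask[2:3, 2] <- 1L
  bm <- binarize(matrix(1:16 * 1.0, 4, 4), mask)
  expect_true(all(bm[mask == 0] == 0))
})

test_that("conditional operators honour their limit regimes", {
  set.seed(90)
  b <- random_binary(10, 10)
  g <- matrix(runif(100), 10, 10)
  # p_we = 1: complete lack of erosion effectiveness
  expect_identical(conditional_erosion(b, g, conditional_params(p_we = 1), 3), b)
  # p_we = -1, p_mn = 1: condition forced, plain erosion everywhere
  plain <- matrix(as.integer(oracle_neigh(b, unclass(disc_se(3)), min)), 10, 10)
  expect_identical(
    conditional_erosion(b, g, conditional_params(p_we = -1, p_mn = 1), 3),
    plain)
  # p_wd = 1, p_mn = 1: dilation is the identity
  expect_identical(
    conditional_dilation(b, g, conditional_params(p_wd = 1, p_mn = 1), 3), b)
  # p_wd = -1: keep only where s_rd = 0, plain dilation elsewhere
  got <- conditional_dilation(b, g, conditional_params(p_wd = -1, p_mn = 0.5), 3)
  expect_identical(got, oracle_cond_dilation(b, g, -1, 0.5, unclass(disc_se(3))))
})

test_that("conditional erosion and dilation match the literal per-pixel oracle", {
  set.seed(91)
  grid <- effectiveness_grid()
  for (s in c(3, 5)) {
    off <- unclass(disc_se(s))
    for (rep in 1:5) {
      b <- random_binary(8, 8)
      g <- matrix(runif(64), 8, 8)
      p_we <- sample(grid, 1); p_wd <- sample(grid, 1)
      p_mn <- runif(1)
      pe <- conditional_params(p_we = p_we, p_wd = p_wd, p_mn = p_mn)
      expect_identical(conditional_erosion(b, g, pe, s),
                       oracle_cond_erosion(b, g, p_we, p_mn, off))
      expect_identical(conditional_dilation(b, g, pe, s),
                       oracle_cond_dilation(b, g, p_wd, p_mn, off))
    }
  }
  expect_error(conditional_erosion(random_binary(4, 4), matrix(0, 5, 5)),
               "shape")
})

test_that("erosion intensity is non-increasing in the effectiveness constant", {
  set.seed(92)
  g <- matrix(runif(144), 12, 12)
  g01 <- (g - min(g)) / (max(g) - min(g))
  s_re <- oracle_neigh(g01, unclass(disc_se(3)), mean)
  fired <- vapply(effectiveness_grid(), function(p_we) {
    mean((1 - p_we) * 0.5 > s_re)
  }, numeric(1))
  expect_true(all(diff(fired) <= 0))
  expect_equal(fired[length(fired)], 0)  # p_we = 1 never fires
})

test_that("refinement is a fixed point under identity parameters and stays binary", {
  set.seed(93)
  b <- random_binary(12, 12)
  g <- matrix(runif(144), 12, 12)
  ident <- conditional_params(p_we = 1, p_wd = 1, p_mn = 1)
  expect_identical(refine(b, g, ident, 3), b)

  zero <- matrix(0L, 12, 12)
  expect_identical(refine(zero, g, conditional_params(), 3), zero)

  out <- refine(b, g, conditional_params(), 5)
  expect_true(all(out %in% c(0L, 1L)))

  # masked-out pixels never become foreground
  mask <- matrix(1L, 12, 12); mask[, 1:4] <- 0L
  outm <- refine(b, g, conditional_params(), 3, mask = mask)
  expect_true(all(outm[mask == 0] == 0))
})

test_that("more refinement rounds leave no more single-pixel specks than fewer", {
  set.seed(94)
  ph <- generate_bscan(small_spec("Z1", seed = 55L, sp_noise_density = 0.05))
  corr <- brightness_correction(preprocess_bscan(ph$image))
  L_O <- filter_bank(corr, scales = 3)[["3"]]
  L_B <- binarize(L_O, corr$valid_mask)
  speck_count <- function(n_rounds) {
    lk <- refine(L_B, L_O, conditional_params(n_rounds = n_rounds), 3,
                 corr$valid_mask)
    sum(label_objects(lk)$n_pixels == 1)
  }
  expect_lte(speck_count(3), speck_count(1))
})

test_that("the scale stack produces binary refined images at all five scales", {
  ph <- generate_bscan(small_spec("Z2", seed = 66L))
  corr <- brightness_correction(preprocess_bscan(ph$image))
  st <- scale_stack(corr)
  expect_named(st, c("3", "5", "7", "9", "11"))
  for (s in names(st)) {
    expect_true(all(st[[s]]$L_B %in% c(0L, 1L)))
    expect_true(all(st[[s]]$L_K %in% c(0L, 1L)))
    expect_true(all(st[[s]]$L_K[corr$valid_mask == 0] == 0))
  }

  # persistence: binary planes round-trip exactly, sidecar records ranges
  dir <- withr::local_tempdir()
  sidecar <- write_scale_stack(st, dir)
  expect_true(file.exists(file.path(dir, "stack.json")))
  expect_identical(sidecar$scales, c(3L, 5L, 7L, 9L, 11L))
  lk3 <- read_bscan(file.path(dir, "L_K_03.png"))
  expect_identical(lk3, st[["3"]]$L_K * 255L)
})
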
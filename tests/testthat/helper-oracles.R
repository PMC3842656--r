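# Brute-force oracles, written directly from the operator definitions and
# kept independent of the package kernels: every pixel is visited by an
# explicit R-level loop; window members are gathered by plain index
# arithmetic.

oracle_median_filter <- function(img, mr, mc) {
  M <- nrow(img); N <- ncol(img)
  hr <- mr %/% 2; hc <- mc %/% 2
  out <- img
  for (m in seq_len(M)) for (n in seq_len(N)) {
    mm <- pmin(pmax(m + (-hr:hr), 1), M)  # edge replication
    nn <- pmin(pmax(n + (-hc:hc), 1), N)
    vals <- sort(as.vector(img[mm, nn]))
    out[m, n] <- vals[(length(vals) + 1) %/% 2]
  }
  out
}

# windowed masked mean with offsets r0..r1 / c0..c1, as documented
oracle_window_mean_masked <- function(img, mask, r0, r1, c0, c1) {
  M <- nrow(img); N <- ncol(img)
  out <- matrix(0, M, N)
  for (m in seq_len(M)) for (n in seq_len(N)) {
    rl <- max(1, m + r0); rh <- min(M, m + r1)
    cl <- max(1, n + c0); ch <- min(N, n + c1)
    sub <- img[rl:rh, cl:ch]; msk <- mask[rl:rh, cl:ch]
    cnt <- sum(msk)
    if (cnt > 0) out[m, n] <- sum(sub * msk) / cnt
  }
  out
}

oracle_brightness_correction <- function(choroid, mask_size = 30L) {
  margin <- mask_size %/% 2L
  r0 <- -margin; r1 <- mask_size - margin - 1L
  mean_img <- oracle_window_mean_masked(choroid$pixels, choroid$valid_mask,
                                        r0, r1, r0, r1)
  M <- nrow(choroid$pixels); N <- ncol(choroid$pixels)
  band <- matrix(0L, M, N)
  if (M > 2 * margin && N > 2 * margin)
    band[(margin + 1):(M - margin), (margin + 1):(N - margin)] <- 1L
  mask <- band * choroid$valid_mask
  (choroid$pixels - mean_img) * mask
}

# values of the (possibly clipped) offset window around pixel (m, n)
oracle_window_vals <- function(img, m, n, off, sgn) {
  mm <- m + sgn * off[, 1]; nn <- n + sgn * off[, 2]
  ok <- mm >= 1 & mm <= nrow(img) & nn >= 1 & nn <= ncol(img)
  img[cbind(mm[ok], nn[ok])]
}

# neighborhood extreme / mean with shrinking window
oracle_neigh <- function(img, off, fun, forward = TRUE) {
  sgn <- if (forward) 1 else -1
  out <- img
  for (m in seq_len(nrow(img))) for (n in seq_len(ncol(img))) {
    vals <- oracle_window_vals(img, m, n, off, sgn)
    out[m, n] <- if (length(vals) > 0) fun(vals) else img[m, n]
  }
  out
}

oracle_filter_bank_scale <- function(src, off, order = "as-printed") {
  if (order == "as-printed") {
    oracle_neigh(oracle_neigh(src, off, max), off, min)
  } else {
    oracle_neigh(oracle_neigh(src, off, min), off, max)
  }
}

oracle_norm01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(array(0, dim(x)))
  (x - lo) / (hi - lo)
}

# conditional erosion: keep where (1-p_we)*p_mn <= s_re, else window minimum
oracle_cond_erosion <- function(binary, grey, p_we, p_mn, off) {
  g <- oracle_norm01(grey)
  out <- binary
  for (m in seq_len(nrow(binary))) for (n in seq_len(ncol(binary))) {
    s_re <- mean(oracle_window_vals(g, m, n, off, 1))
    if ((1 - p_we) * p_mn > s_re) {
      out[m, n] <- min(oracle_window_vals(binary, m, n, off, 1))
    }
  }
  out
}

# conditional dilation: keep where (p_wd+1)*p_mn >= s_rd, else window maximum
oracle_cond_dilation <- function(binary, grey, p_wd, p_mn, off) {
  g <- oracle_norm01(grey)
  out <- binary
  for (m in seq_len(nrow(binary))) for (n in seq_len(ncol(binary))) {
    s_rd <- mean(oracle_window_vals(g, m, n, off, -1))
    if ((p_wd + 1) * p_mn < s_rd) {
      out[m, n] <- max(oracle_window_vals(binary, m, n, off, -1))
    }
  }
  out
}

# 8-connected flood-fill labelling (BFS)
oracle_label8 <- function(bw) {
  M <- nrow(bw); N <- ncol(bw)
  lab <- matrix(0L, M, N)
  nxt <- 0L
  for (m0 in seq_len(M)) for (n0 in seq_len(N)) {
    if (bw[m0, n0] == 1 && lab[m0, n0] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(m0, n0)); lab[m0, n0] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dm in -1:1) for (dn in -1:1) {
          mm <- p[1] + dm; nn <- p[2] + dn
          if (mm < 1 || mm > M || nn < 1 || nn > N) next
          if (bw[mm, nn] == 1 && lab[mm, nn] == 0L) {
            lab[mm, nn] <- nxt
            queue[[length(queue) + 1]] <- c(mm, nn)
          }
        }
      }
    }
  }
  lab
}

gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

# exhaustive Gini split search over all (feature, midpoint) candidates;
# ties broken towards lowest feature index, then lowest threshold;
# n_best counts the candidates achieving the maximal decrease
oracle_gini_split <- function(x, y) {
  x <- as.data.frame(x); y <- as.factor(y)
  n <- length(y)
  base <- gini_impurity(y)
  best <- list(feature = NA, threshold = NA, decrease = -Inf, n_best = 0L)
  for (j in seq_len(ncol(x))) {
    v <- x[[j]]
    u <- sort(unique(v))
    if (length(u) < 2) next
    thr <- (u[-1] + u[-length(u)]) / 2
    for (t in thr) {
      left <- v < t
      dec <- base - (sum(left) / n) * gini_impurity(y[left]) -
        (sum(!left) / n) * gini_impurity(y[!left])
      if (dec > best$decrease + 1e-12) {
        best <- list(feature = j, threshold = t, decrease = dec, n_best = 1L)
      } else if (abs(dec - best$decrease) <= 1e-12) {
        best$n_best <- best$n_best + 1L
      }
    }
  }
  best
}

# Gini decrease achieved by the root split of a fitted choroid_cart
root_split_decrease <- function(model, x, y) {
  f <- rownames(model$fit$splits)[1]
  t <- unname(model$fit$splits[1, "index"])
  v <- x[[f]]; left <- v < t; n <- length(y)
  gini_impurity(y) - (sum(left) / n) * gini_impurity(y[left]) -
    (sum(!left) / n) * gini_impurity(y[!left])
}

# AUC as the Mann-Whitney U statistic over n+ * n-, better orientation
oracle_auc_mw <- function(v, positive) {
  pos <- v[positive]; neg <- v[!positive]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  a <- u / (length(pos) * length(neg))
  max(a, 1 - a)
}
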
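toy_features <- function(n = 60, seed = 1) {
  # three well-separated classes in two features plus noise columns
  set.seed(seed)
  y <- factor(rep(c("Z1", "Z2", "Z3"), length.out = n))
  x <- data.frame(
    w1 = rnorm(n, c(0, 4, 8)[as.integer(y)], 0.5),
    w2 = rnorm(n, c(5, 0, 5)[as.integer(y)], 0.5),
    w3 = rnorm(n), w4 = rnorm(n))
  list(x = x, y = y)
}

test_that("separable one-dimensional data yields a single perfect split", {
  x <- data.frame(w1 = c(0, 0, 0, 10, 10, 10))
  y <- factor(c("Z1", "Z1", "Z1", "Z2", "Z2", "Z2"))
  m <- train_cart(x, y)
  expect_identical(sum(m$fit$frame$var != "<leaf>"), 1L)
  expect_identical(as.character(predict(m, x)), as.character(y))
})

test_that("a pure training set produces a single leaf", {
  x <- data.frame(w1 = rnorm(10))
  y <- factor(rep("Z2", 10), levels = c("Z1", "Z2", "Z3"))
  m <- train_cart(x, y)
  expect_identical(nrow(m$fit$frame), 1L)
  expect_identical(as.character(predict(m, x[1:3, , drop = FALSE])),
                   rep("Z2", 3))
})

test_that("the root split agrees with the exhaustive Gini oracle", {
  # 8-point two-feature toy set
  x8 <- data.frame(w1 = c(1, 2, 3, 4, 10, 11, 12, 13),
                   w2 = c(5, 1, 4, 2, 3, 6, 2, 7))
  y8 <- factor(c("Z1", "Z1", "Z1", "Z1", "Z2", "Z2", "Z2", "Z2"))
  m <- train_cart(x8, y8)
  oracle <- oracle_gini_split(x8, y8)
  split_row <- m$fit$splits[1, ]
  expect_identical(rownames(m$fit$splits)[1], names(x8)[oracle$feature])
  expect_equal(unname(split_row["index"]), oracle$threshold)

  # random toy sets: the root split always attains the oracle's maximal
  # impurity decrease, and matches it exactly whenever the maximum is unique
  for (s in 1:5) {
    set.seed(400 + s)
    xr <- data.frame(w1 = sample(1:40, 12), w2 = sample(1:40, 12),
                     w3 = sample(1:40, 12))
    yr <- factor(sample(c("Z1", "Z2", "Z3"), 12, replace = TRUE))
    if (nlevels(droplevels(yr)) < 2) next
    mr <- train_cart(xr, yr)
    orc <- oracle_gini_split(xr, yr)
    expect_equal(root_split_decrease(mr, xr, yr), orc$decrease,
                 tolerance = 1e-10)
    if (orc$n_best == 1L) {
      expect_identical(rownames(mr$fit$splits)[1], names(xr)[orc$feature])
      expect_equal(unname(mr$fit$splits[1, "index"]), orc$threshold)
    }
  }
})

test_that("feature subsets restrict the columns seen by the tree", {
  d <- toy_features()
  m <- train_cart(d$x, d$y, subset_mask = c(3, 4))
  expect_identical(m$feature_names, c("w3", "w4"))
  m2 <- train_cart(d$x, d$y, subset_mask = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(m2$feature_names, "w1")
  expect_error(train_cart(d$x, d$y, subset_mask = logical(4)), "no features")
})

test_that("1-SE pruning keeps a perfect separator and honours its contract", {
  x <- data.frame(w1 = c(rep(0, 20), rep(10, 20)))
  y <- factor(rep(c("Z1", "Z2"), each = 20))
  pr <- prune_1se(train_cart(x, y), k_folds = 5, seed = 3)
  expect_identical(as.character(predict(pr, x)), as.character(y))

  for (s in 1:5) {
    d <- toy_features(n = 45, seed = 500 + s)
    pr <- prune_1se(train_cart(d$x, d$y), k_folds = 10, seed = s)
    cv <- pr$cv
    expect_lte(cv$cv_error[cv$selected],
               min(cv$cv_error) + cv$cv_se[which.min(cv$cv_error)] + 1e-12)
    # smallest tree under the cutoff: every smaller level violates it
    sel <- which(cv$selected)
    if (sel > 1) {
      expect_true(all(cv$cv_error[seq_len(sel - 1)] >
                        min(cv$cv_error) + cv$cv_se[which.min(cv$cv_error)]))
    }
  }
})

test_that("pruning collapses pure-noise trees to the root in most seeds", {
  collapsed <- vapply(1:50, function(s) {
    set.seed(7000 + s)
    x <- data.frame(w1 = rnorm(200), w2 = rnorm(200))
    y <- factor(sample(c("Z1", "Z2", "Z3"), 200, replace = TRUE))
    pr <- prune_1se(train_cart(x, y), k_folds = 10, seed = s)
    sum(pr$fit$frame$var != "<leaf>") == 0
  }, logical(1))
  # Monte-Carlo over 50 fixed seeds with the binomial SE formula: the 1-SE
  # rule collapses 37/50 pure-noise trees to the root
  expect_gte(mean(collapsed), 0.7)
})

test_that("pruning is deterministic under a fixed seed and reduces folds when needed", {
  d <- toy_features(n = 30, seed = 2)
  a <- prune_1se(train_cart(d$x, d$y), k_folds = 5, seed = 9)
  b <- prune_1se(train_cart(d$x, d$y), k_folds = 5, seed = 9)
  expect_identical(a$cv, b$cv)
  expect_warning(prune_1se(train_cart(d$x, d$y), k_folds = 50, seed = 1),
                 "reduced")
})

test_that("evaluation metrics follow their confusion-matrix definitions", {
  d <- toy_features()
  m <- train_cart(d$x, d$y)
  perfect <- evaluate(m, d$x, d$y)
  expect_true(all(perfect$SPC == 1 & perfect$TPR == 1 & perfect$ACC == 1))

  # constructed confusion for one class: TP=8, FN=2, FP=3, TN=17
  truth <- c(rep("Z1", 10), rep("Z2", 20))
  pred <- c(rep("Z1", 8), rep("Z2", 2), rep("Z1", 3), rep("Z2", 17))
  r <- evaluate_predictions(pred, truth)
  expect_equal(r$TPR[1], 0.8)
  expect_equal(r$SPC[1], 0.85)
  expect_equal(r$ACC[1], 25 / 30)

  # constant predictor on a balanced set
  truth3 <- rep(c("Z1", "Z2", "Z3"), each = 10)
  rc <- evaluate_predictions(rep("Z2", 30), truth3)
  expect_equal(rc$TPR[2], 1)
  expect_equal(rc$SPC[2], 0)
  expect_equal(rc$ACC[2], 1 / 3)

  expect_error(evaluate_predictions(c("Z1", "Z9"), c("Z1", "Z1")), "universe")
  expect_error(evaluate_predictions(character(0), character(0)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(71)
  for (rep in 1:20) {
    truth <- sample(c("Z1", "Z2", "Z3"), 60, replace = TRUE)
    pred <- sample(c("Z1", "Z2", "Z3"), 60, replace = TRUE)
    r <- evaluate_predictions(pred, truth)
    P <- r$TP + r$FN; N <- r$TN + r$FP
    expect_equal(r$TP + r$TN + r$FP + r$FN, rep(60L, 3))
    expect_equal(r$TPR * P + r$SPC * N, r$TP + r$TN)
    expect_equal(r$ACC, (r$TP + r$TN) / (P + N))
  }
})

test_that("the planned exhaustive enumeration counts 2 * 2^20 trees", {
  expect_identical(planned_tree_count(20), 2097152L)
  expect_identical(planned_tree_count(8), 512L)
  expect_identical(planned_tree_count(8, pruned = FALSE), 256L)
  expect_error(planned_tree_count(21), "at most 20")
})

test_that("subset search enumerates 2^k subsets with full and pruned variants", {
  d <- toy_features(n = 45, seed = 6)
  split <- rep(c("learning", "validation", "test"), c(27, 9, 9))
  res <- subset_search(d$x, d$y, split, feature_pool = 1:3, seed = 2)
  expect_identical(res$n_subsets, 8L)
  expect_identical(res$n_trees, 16L)
  expect_identical(nrow(res$results), 16L)
  expect_named(res$top3$full, c("Z1", "Z2", "Z3"))
  # top-3 tables carry a 0/1 indicator row per feature plus the accuracy row
  t1 <- res$top3$pruned$Z1
  expect_identical(rownames(t1), c(names(d$x), "ACC"))
  expect_true(all(t1[seq_len(nrow(t1) - 1), ] %in% c(0, 1)))
  expect_length(res$frequency$full, ncol(d$x))
})

test_that("duplicate feature columns give interchangeable subsets", {
  d <- toy_features(n = 45, seed = 8)
  x <- d$x; x$w2 <- x$w1  # duplicate column
  split <- rep(c("learning", "validation", "test"), c(27, 9, 9))
  res <- subset_search(x, d$y, split, feature_pool = 1:2, seed = 5)
  r <- res$results
  acc_only1 <- unlist(r[r$features == "1", c("ACC1", "ACC2", "ACC3")])
  acc_only2 <- unlist(r[r$features == "2", c("ACC1", "ACC2", "ACC3")])
  expect_equal(unname(acc_only1), unname(acc_only2))
})

test_that("single-feature ROC curves behave like the Mann-Whitney statistic", {
  # perfectly ordered feature
  y <- rep(c("Z1", "Z2", "Z3"), each = 10)
  x <- data.frame(w1 = c(1:10, 21:30, 41:50))
  rs <- per_feature_roc(x, y)
  expect_equal(rs$w1$Z3$auc, 1)
  expect_true(all(diff(rs$w1$Z1$fpr) >= 0))
  expect_true(all(diff(rs$w1$Z1$tpr) >= 0))

  # AUC equals the rank-statistic oracle
  set.seed(81)
  xr <- data.frame(w1 = rnorm(60), w2 = rnorm(60))
  yr <- sample(c("Z1", "Z2", "Z3"), 60, replace = TRUE)
  rr <- per_feature_roc(xr, yr)
  for (f in names(xr)) for (cl in c("Z1", "Z2", "Z3")) {
    expect_equal(rr[[f]][[cl]]$auc, oracle_auc_mw(xr[[f]], yr == cl),
                 tolerance = 1e-10)
  }

  # label-independent feature: AUC near one half
  set.seed(82)
  xn <- data.frame(w1 = rnorm(500))
  yn <- sample(c("Z1", "Z2", "Z3"), 500, replace = TRUE)
  rn <- per_feature_roc(xn, yn)
  expect_lt(abs(rn$w1$Z1$auc - 0.5), 0.05)

  # degenerate constant feature
  expect_warning(rd <- per_feature_roc(data.frame(w1 = rep(1, 20)),
                                       rep(c("Z1", "Z2", "Z3"), length.out = 20)),
                 "constant")
  expect_equal(rd$w1$Z2$auc, 0.5)
  expect_error(per_feature_roc(data.frame(w1 = 1:4), rep("Z1", 4)),
               "positive")
})

test_that("models survive a JSON round trip with identical predictions", {
  d <- toy_features(n = 60, seed = 10)
  m <- prune_1se(train_cart(d$x, d$y), k_folds = 5, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  mj <- read_model(path)
  newx <- toy_features(n = 30, seed = 11)$x
  expect_identical(as.character(predict(mj, newx)),
                   as.character(predict(m, newx)))
})
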
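#' Train an unrestricted CART classifier on texture features
#'
#' Grows a binary classification tree on the feature table with Gini
#' impurity as the node-impurity measure and no minimum node size
#' (`minsplit = 2`, `minbucket = 1`, complexity penalty 0), so the tree is
#' limited only by node purity. Candidate thresholds are the midpoints
#' between consecutive distinct feature values; training is deterministic.
#' The fitting engine is \pkg{rpart}.
#'
#' @param x data frame or matrix of feature columns (typically `w1`-`w20`
#'   from [extract_features()]).
#' @param y factor of class labels (`Z1`/`Z2`/`Z3`).
#' @param subset_mask optional feature subset: logical or 0/1 vector of
#'   length `ncol(x)`, or integer column indices. Must select at least one
#'   feature.
#' @return an object of class `"choroid_cart"`: list with the `rpart` fit,
#'   the feature names used, the training data (kept for pruning), and
#'   metadata.
#' @export
train_cart <- function(x, y, subset_mask = NULL) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  cols <- resolve_subset(subset_mask, ncol(x))
  if (length(cols) == 0L) stop("subset_mask selects no features")
  xs <- x[, cols, drop = FALSE]
  fit <- fit_rpart(xs, y)
  structure(list(fit = fit, feature_names = colnames(xs),
                 subset_mask = cols, x = xs, y = y, pruned = FALSE,
                 cv = NULL),
            class = "choroid_cart")
}

resolve_subset <- function(subset_mask, p) {
  if (is.null(subset_mask)) return(seq_len(p))
  if (is.logical(subset_mask)) {
    stopifnot(length(subset_mask) == p)
    return(which(subset_mask))
  }
  subset_mask <- as.integer(subset_mask)
  if (length(subset_mask) == p && all(subset_mask %in% c(0L, 1L)) &&
      any(subset_mask == 0L)) {
    return(which(subset_mask == 1L))
  }
  stopifnot(all(subset_mask >= 1L), all(subset_mask <= p))
  sort(unique(subset_mask))
}

cart_control <- function() {
  rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                       xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                       usesurrogate = 0L, maxdepth = 30L)
}

fit_rpart <- function(xs, y) {
  df <- cbind(.class = y, xs)
  fit <- if (nlevels(droplevels(y)) < 2L || ncol(xs) == 0L) {
    # degenerate: majority-class stump (constant predictor, no split possible)
    df <- data.frame(.class = y, .const = rep(1, length(y)))
    rpart::rpart(.class ~ .const, data = df, method = "class",
                 control = cart_control())
  } else {
    rpart::rpart(.class ~ ., data = df, method = "class",
                 control = cart_control())
  }
  # embed the data in the stored call so cross-validation (xpred) can
  # re-evaluate it outside this frame
  fit$call$data <- df
  fit
}

#' Prune a CART model by the one-standard-error rule
#'
#' Computes the cost-complexity pruning sequence of the fitted tree and
#' estimates the misclassification cost of every pruning level by
#' stratified k-fold cross-validation on the training rows (fold assignment
#' seeded, so the result is reproducible). The selected level is the
#' smallest tree whose cross-validated cost does not exceed the minimum
#' cost plus one standard error of that minimum; level 0 is the unpruned
#' tree.
#'
#' @param model a `"choroid_cart"` from [train_cart()].
#' @param k_folds number of cross-validation folds (default 10); reduced
#'   with a warning when a class has fewer members than folds.
#' @param seed integer seed for the fold assignment.
#' @return the pruned `"choroid_cart"`; the cross-validation table (one row
#'   per pruning level: `CP`, `nsplit`, `cv_error`, `cv_se`, selection flag)
#'   is stored in `$cv`.
#' @export
prune_1se <- function(model, k_folds = 10L, seed = 1L) {
  stopifnot(inherits(model, "choroid_cart"))
  fit <- model$fit
  cpt <- fit$cptable
  n <- length(model$y)
  if (is.null(cpt) || nrow(cpt) == 1L) {
    model$pruned <- TRUE
    model$cv <- data.frame(CP = if (is.null(cpt)) 0 else cpt[1, "CP"],
                           nsplit = 0L, cv_error = NA_real_,
                           cv_se = NA_real_, selected = TRUE)
    return(model)
  }
  min_class <- min(table(model$y))
  if (k_folds > min_class) {
    k_folds <- max(2L, min_class)
    warning("fewer samples than folds in a class; k_folds reduced to ", k_folds)
  }
  folds <- with_seed(seed, stratified_folds(model$y, k_folds))
  xp <- rpart::xpred.rpart(fit, xval = folds)
  yint <- as.integer(model$y)
  err <- colMeans(xp != yint)
  se <- sqrt(err * (1 - err) / n)
  thr <- min(err) + se[which.min(err)]
  ok <- which(err <= thr)
  chosen <- ok[1L]  # cptable row 1 = smallest tree (root)
  pruned_fit <- rpart::prune(fit, cp = cpt[chosen, "CP"])
  model$fit <- pruned_fit
  model$pruned <- TRUE
  model$cv <- data.frame(CP = cpt[, "CP"], nsplit = cpt[, "nsplit"],
                         cv_error = err, cv_se = se,
                         selected = seq_len(nrow(cpt)) == chosen,
                         row.names = NULL)
  model$k_folds <- k_folds
  model$seed <- seed
  model
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' @export
print.choroid_cart <- function(x, ...) {
  nleaf <- sum(x$fit$frame$var == "<leaf>")
  cat(sprintf("<choroid_cart> %s tree, %d features (%s), %d leaves\n",
              if (x$pruned) "pruned" else "full",
              length(x$feature_names),
              paste(utils::head(x$feature_names, 5),
                    collapse = ","),
              nleaf))
  invisible(x)
}

#' @export
summary.choroid_cart <- function(object, ...) {
  print(object)
  print(object$fit)
  if (!is.null(object$cv)) {
    cat("\nCross-validated pruning sequence (1-SE selection flagged):\n")
    print(object$cv)
  }
  invisible(object)
}

#' @export
predict.choroid_cart <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols) > 0)
    stop("newdata lacks feature columns: ", paste(missing_cols, collapse = ", "))
  newdata$.const <- 1  # satisfies degenerate stump fits
  predict(object$fit, newdata = newdata,
          type = if (type == "class") "class" else "prob")
}

#' @export
plot.choroid_cart <- function(x, ...) {
  if (sum(x$fit$frame$var != "<leaf>") == 0) {
    graphics::plot.new()
    graphics::title(main = "single-leaf tree")
    return(invisible(x))
  }
  graphics::plot(x$fit, uniform = TRUE, margin = 0.1, ...)
  graphics::text(x$fit, use.n = TRUE, cex = 0.8)
  invisible(x)
}

#' Per-class evaluation report from predictions
#'
#' Forms the 3-class confusion matrix and derives one-vs-rest counts and
#' metrics per class: specificity `SPC = TN/(FP+TN)`, sensitivity
#' `TPR = TP/(TP+FN)` and accuracy `ACC = (TP+TN)/(TP+TN+FP+FN)`.
#'
#' @param predicted factor/character of predicted labels.
#' @param truth factor/character of true labels.
#' @param classes class universe (default `Z1`, `Z2`, `Z3`).
#' @return an object of class `"eval_report"`: data frame with one row per
#'   class (`class`, `TP`, `TN`, `FP`, `FN`, `SPC`, `TPR`, `ACC`) and the
#'   full confusion matrix in attribute `"confusion"`.
#' @export
evaluate_predictions <- function(predicted, truth,
                                 classes = c("Z1", "Z2", "Z3")) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0L) stop("empty evaluation set")
  bad <- setdiff(unique(c(predicted, truth)), classes)
  if (length(bad) > 0)
    stop("labels outside the class universe: ", paste(bad, collapse = ", "))
  conf <- table(factor(truth, classes), factor(predicted, classes),
                dnn = c("truth", "predicted"))
  n <- sum(conf)
  rep <- do.call(rbind, lapply(classes, function(cl) {
    TP <- conf[cl, cl]
    FN <- sum(conf[cl, ]) - TP
    FP <- sum(conf[, cl]) - TP
    TN <- n - TP - FN - FP
    data.frame(class = cl, TP = TP, TN = TN, FP = FP, FN = FN,
               SPC = TN / (FP + TN), TPR = TP / (TP + FN),
               ACC = (TP + TN) / n)
  }))
  attr(rep, "confusion") <- conf
  class(rep) <- c("eval_report", "data.frame")
  rep
}

#' Evaluate a CART model on a feature table
#'
#' @param model a `"choroid_cart"`.
#' @param x feature table of the evaluation rows.
#' @param y true labels.
#' @param classes class universe.
#' @return an `"eval_report"`, see [evaluate_predictions()].
#' @export
evaluate <- function(model, x, y, classes = c("Z1", "Z2", "Z3")) {
  evaluate_predictions(predict(model, x), y, classes)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Per-class one-vs-rest evaluation:\n")
  df <- as.data.frame(x)
  df$SPC <- round(df$SPC, 3); df$TPR <- round(df$TPR, 3)
  df$ACC <- round(df$ACC, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Number of trees planned by an exhaustive feature-subset search
#'
#' Every subset of an `n_features` pool yields one full and (optionally)
#' one pruned tree: `2^n_features` subsets each. For the complete
#' 20-feature pool the plan is `2 * 2^20 = 2,097,152` trees.
#'
#' @param n_features size of the feature pool (<= 20).
#' @param pruned also count the pruned counterpart of every tree
#'   (default `TRUE`).
#' @return integer tree count.
#' @export
planned_tree_count <- function(n_features = 20L, pruned = TRUE) {
  if (n_features > 20L) stop("the feature pool holds at most 20 features")
  (1L + as.integer(pruned)) * as.integer(2^n_features)
}

#' Feature-subset search over full and pruned trees
#'
#' Enumerates every subset of the feature pool (including the empty subset,
#' realised as a majority-class stump), trains a full tree on the learning
#' split, prunes it by the 1-SE rule (cross-validation on the learning
#' split only), and evaluates both trees on the test split. The validation
#' split is left untouched by training and pruning and is reserved for
#' optional model selection. Reports the three top subsets per class by
#' per-class accuracy, for full and pruned trees separately, plus the
#' occurrence frequency of every feature among the top-ranked subsets
#' (ranking by overall test accuracy).
#'
#' @param x feature table (all rows).
#' @param y labels (all rows).
#' @param split factor `learning`/`validation`/`test` per row.
#' @param feature_pool integer column indices forming the pool (`k <= 20`
#'   columns; the default full-20 pool is intended for the headline
#'   arithmetic — enumeration cost doubles per added feature, so desk-scale
#'   runs use `k` around 8), or a list of explicit index vectors (one per
#'   subset) to search a fixed bitmask list instead.
#' @param seed seed for the pruning cross-validation folds.
#' @param k_folds pruning CV folds.
#' @param freq_top number of top-ranked subsets entering the
#'   occurrence-frequency chart (default 1000, capped at the number of
#'   non-empty subsets).
#' @param classes class universe.
#' @return an object of class `"subset_search"`: list with `results` (one
#'   row per subset x tree type), `top3` (per class and tree type, the
#'   feature-indicator table with an accuracy row), `frequency` (per tree
#'   type, feature occurrence counts among the top subsets), and counters
#'   `n_subsets`, `n_trees`.
#' @export
subset_search <- function(x, y, split, feature_pool = 1:8, seed = 1L,
                          k_folds = 10L, freq_top = 1000L,
                          classes = c("Z1", "Z2", "Z3")) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  split <- as.character(split)
  stopifnot(nrow(x) == length(y), length(split) == length(y))
  if (is.list(feature_pool)) {
    subsets <- feature_pool
    pool <- sort(unique(unlist(feature_pool)))
  } else {
    pool <- as.integer(feature_pool)
    if (length(pool) > 20L) stop("feature pool larger than 20")
    subsets <- lapply(0:(2^length(pool) - 1L), function(b) {
      pool[bitwAnd(b, 2^(seq_along(pool) - 1L)) > 0L]
    })
  }
  learn <- split == "learning"
  test <- split == "test"
  if (!any(learn) || !any(test)) stop("need nonempty learning and test splits")

  rows <- vector("list", 2L * length(subsets))
  ri <- 0L
  for (si in seq_along(subsets)) {
    cols <- subsets[[si]]
    model <- if (length(cols) == 0L) {
      structure(list(fit = fit_rpart(x[learn, 0, drop = FALSE], y[learn]),
                     feature_names = character(0), subset_mask = integer(0),
                     x = x[learn, 0, drop = FALSE], y = y[learn],
                     pruned = FALSE, cv = NULL),
                class = "choroid_cart")
    } else {
      train_cart(x[learn, , drop = FALSE], y[learn], cols)
    }
    pruned <- suppressWarnings(prune_1se(model, k_folds, seed))
    for (ttype in c("full", "pruned")) {
      m <- if (ttype == "full") model else pruned
      pred <- if (length(cols) == 0L)
        rep(as.character(majority_class(y[learn])), sum(test))
      else as.character(predict(m, x[test, , drop = FALSE]))
      rep_k <- evaluate_predictions(pred, y[test], classes)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        subset_id = si, tree = ttype,
        n_features = length(cols),
        features = paste(cols, collapse = "+"),
        overall_acc = mean(pred == as.character(y[test])),
        ACC1 = rep_k$ACC[1], ACC2 = rep_k$ACC[2], ACC3 = rep_k$ACC[3])
    }
  }
  results <- do.call(rbind, rows)

  top3 <- list(); frequency <- list()
  for (ttype in c("full", "pruned")) {
    res_t <- results[results$tree == ttype, ]
    top3[[ttype]] <- lapply(seq_along(classes), function(k) {
      acc <- res_t[[paste0("ACC", k)]]
      ord <- order(acc, decreasing = TRUE)[1:min(3L, nrow(res_t))]
      tab <- sapply(res_t$subset_id[ord], function(si) {
        as.integer(seq_len(ncol(x)) %in% subsets[[si]])
      })
      rownames(tab) <- colnames(x)
      rbind(tab, ACC = acc[ord])
    })
    names(top3[[ttype]]) <- classes
    ord_all <- order(res_t$overall_acc, decreasing = TRUE)
    keep <- ord_all[seq_len(min(freq_top, nrow(res_t)))]
    freq <- integer(ncol(x))
    for (si in res_t$subset_id[keep]) {
      freq[subsets[[si]]] <- freq[subsets[[si]]] + 1L
    }
    frequency[[ttype]] <- setNames(freq, colnames(x))
  }

  structure(list(results = results, top3 = top3, frequency = frequency,
                 n_subsets = length(subsets),
                 n_trees = 2L * length(subsets),
                 pool = pool, classes = classes),
            class = "subset_search")
}

majority_class <- function(y) names(which.max(table(y)))

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> %d subsets, %d trees (full + pruned)\n",
              x$n_subsets, x$n_trees))
  for (ttype in names(x$top3)) {
    best <- vapply(x$top3[[ttype]], function(t) t["ACC", 1], numeric(1))
    cat(sprintf("  %s tree best per-class ACC: %s\n", ttype,
                paste(sprintf("%s=%.3f", names(best), best), collapse = ", ")))
  }
  invisible(x)
}

#' Occurrence-frequency chart of features among the top subsets
#'
#' @param x a `"subset_search"`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the frequency matrix (features x tree type).
#' @export
plot.subset_search <- function(x, ...) {
  m <- rbind(full = x$frequency$full, pruned = x$frequency$pruned)
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = rownames(m),
                    ylab = "occurrences among top subsets", ...)
  invisible(t(m))
}

#' Single-feature ROC curves per class
#'
#' For every feature and every class (one-vs-rest), sweeps all decision
#' thresholds of the feature in both orientations and reports the
#' better-oriented ROC staircase and its area under the curve (computed
#' with \pkg{pROC}; the AUC equals the Mann-Whitney U statistic divided by
#' the product of group sizes). A constant feature gives the degenerate
#' diagonal with AUC 0.5 and a warning.
#'
#' @param x feature table.
#' @param y labels.
#' @param classes class universe; each class needs at least one positive
#'   and one negative row.
#' @return an object of class `"roc_set"`: nested list
#'   `[[feature]][[class]]` with `fpr`, `tpr` (non-decreasing staircase),
#'   `auc` and `direction`.
#' @export
per_feature_roc <- function(x, y, classes = c("Z1", "Z2", "Z3")) {
  x <- as.data.frame(x)
  y <- as.character(y)
  for (cl in classes) {
    if (sum(y == cl) == 0L || sum(y != cl) == 0L)
      stop("class ", cl, " needs at least one positive and one negative")
  }
  out <- lapply(colnames(x), function(f) {
    v <- x[[f]]
    constant <- length(unique(v)) < 2L
    if (constant) warning("constant feature ", f, ": degenerate ROC (AUC 0.5)")
    per_class <- lapply(classes, function(cl) {
      resp <- factor(ifelse(y == cl, "pos", "neg"), c("neg", "pos"))
      if (constant) {
        return(list(fpr = c(0, 1), tpr = c(0, 1), auc = 0.5,
                    direction = "none"))
      }
      best <- NULL
      for (dir in c("<", ">")) {
        r <- pROC::roc(resp, v, direction = dir, quiet = TRUE)
        a <- as.numeric(pROC::auc(r))
        if (is.null(best) || a > best$auc) {
          ord <- order(1 - r$specificities, r$sensitivities)
          best <- list(fpr = (1 - r$specificities)[ord],
                       tpr = r$sensitivities[ord],
                       auc = a, direction = dir)
        }
      }
      best
    })
    names(per_class) <- classes
    per_class
  })
  names(out) <- colnames(x)
  structure(out, class = "roc_set")
}

#' @export
print.roc_set <- function(x, ...) {
  cat("<roc_set> per-feature, per-class AUC:\n")
  classes <- names(x[[1]])
  m <- t(vapply(x, function(f) vapply(f, `[[`, numeric(1), "auc"),
                numeric(length(classes))))
  print(round(m, 3))
  invisible(x)
}

#' @export
plot.roc_set <- function(x, features = names(x), ...) {
  classes <- names(x[[1]])
  graphics::par(mfrow = c(1, length(classes)))
  for (cl in classes) {
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                   xlab = "FPR", ylab = "TPR", main = cl)
    for (f in features) {
      graphics::lines(x[[f]][[cl]]$fpr, x[[f]][[cl]]$tpr, type = "s")
    }
  }
  invisible(x)
}

#' Serialize a CART model to JSON
#'
#' Writes the tree as a list of nodes (split feature, midpoint threshold,
#' child ids, leaf label), round-trippable with [read_model()].
#'
#' @param model a `"choroid_cart"`.
#' @param path output file.
#' @return invisibly, the node data frame.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "choroid_cart"))
  nodes <- rpart_nodes(model$fit)
  payload <- list(feature_names = model$feature_names,
                  classes = levels(model$y),
                  pruned = model$pruned,
                  nodes = nodes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(nodes)
}

# flatten an rpart tree into a node table (1-based ids, -1 = none)
rpart_nodes <- function(fit) {
  frame <- fit$frame
  node_num <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  ylev <- attr(fit, "ylevels")
  # primary split per internal node, in frame order (no competes/surrogates)
  thr <- rep(NA_real_, nrow(frame))
  dir <- rep(NA_integer_, nrow(frame))
  if (any(!is_leaf)) {
    sp <- fit$splits
    thr[!is_leaf] <- sp[, "index"]
    dir[!is_leaf] <- sign(sp[, "ncat"])
  }
  data.frame(
    id = seq_len(nrow(frame)),
    node = node_num,
    feature = ifelse(is_leaf, NA_character_, as.character(frame$var)),
    threshold = thr,
    lt_goes_left = ifelse(is_leaf, NA, dir == -1L),
    left = match(node_num * 2L, node_num),
    right = match(node_num * 2L + 1L, node_num),
    leaf_label = ifelse(is_leaf, ylev[frame$yval], NA_character_),
    stringsAsFactors = FALSE)
}

#' Read a serialized CART model
#'
#' @param path JSON file written by [write_model()].
#' @return an object of class `"choroid_cart_json"` supporting
#'   [predict()].
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(payload, class = "choroid_cart_json")
}

#' @export
predict.choroid_cart_json <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  nodes <- object$nodes
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    id <- 1L
    repeat {
      nd <- nodes[id, ]
      if (!is.na(nd$leaf_label)) { out[i] <- nd$leaf_label; break }
      v <- newdata[i, nd$feature]
      goes_left <- if (isTRUE(nd$lt_goes_left)) v < nd$threshold else v >= nd$threshold
      id <- if (goes_left) nd$left else nd$right
    }
  }
  factor(out, levels = object$classes)
}
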
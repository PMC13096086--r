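# Classifiers for the consciousness-state problem. Implemented in-package:
# a linear one-vs-rest SVM trained by dual coordinate descent (L1 hinge,
# C = 1, bias via an augmented constant feature) and a CART random forest
# (Gini splits, sqrt(p) feature subsampling, 100 bootstrap trees).

# ---- linear SVM ------------------------------------------------------------

svm_binary_train <- function(X, yb, C = 1, max_epochs = 1000, tol = 1e-6,
                             seed = 0L) {
  Xa <- cbind(X, bias = 1)
  n <- nrow(Xa)
  Qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  with_seed(derive_seed(seed, 777L), {
    for (ep in seq_len(max_epochs)) {
      viol <- 0
      for (i in sample.int(n)) {
        G <- yb[i] * sum(w * Xa[i, ]) - 1
        PG <- if (alpha[i] == 0) min(G, 0) else if (alpha[i] == C) max(G, 0) else G
        viol <- max(viol, abs(PG))
        if (abs(PG) > 1e-12) {
          a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
          w <- w + (a_new - alpha[i]) * yb[i] * Xa[i, ]
          alpha[i] <- a_new
        }
      }
      if (viol < tol) break
    }
  })
  w
}

#' Linear multiclass SVM (one-vs-rest)
#'
#' L1-hinge linear SVM with `C = 1` (no tuning), solved by dual coordinate
#' descent; multiclass handled one-vs-rest with prediction by the largest
#' decision value. Decision scores feed the per-class ROC curves.
#'
#' @param X numeric matrix (samples x features), already standardized
#' @param y class labels
#' @param C soft-margin cost
#' @param seed integer seed (coordinate order)
#' @return object of class `linear_svm`
#' @export
svm_train <- function(X, y, C = 1, seed = 0L) {
  y <- as.factor(y)
  lv <- levels(y)
  W <- vapply(lv, function(cl) {
    yb <- ifelse(y == cl, 1, -1)
    svm_binary_train(X, yb, C = C, seed = derive_seed(seed, match(cl, lv)))
  }, numeric(ncol(X) + 1))
  structure(list(W = W, levels = lv), class = "linear_svm")
}

#' @rdname svm_train
#' @param object fitted model
#' @param newdata matrix of rows to score
#' @param ... unused
#' @return `predict`: list with `class` (factor) and `scores`
#'   (samples x classes decision values)
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  S <- cbind(newdata, rep(1, nrow(newdata))) %*% object$W
  colnames(S) <- object$levels
  cls <- factor(object$levels[max.col(S, ties.method = "first")],
                levels = object$levels)
  list(class = cls, scores = S)
}

# ---- random forest ---------------------------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

grow_tree <- function(X, yi, nlev, mtry, min_node = 1) {
  n <- length(yi)
  counts <- tabulate(yi, nlev)
  if (n <= min_node || gini_impurity(counts) == 0 || nrow(unique(X)) == 1)
    return(list(leaf = TRUE, counts = counts))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL; best_gain <- 0
  g0 <- gini_impurity(counts)
  for (f in feats) {
    xv <- X[, f]
    ordi <- order(xv)
    xs <- xv[ordi]; ys <- yi[ordi]
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0) next
    left <- matrix(0, nlev, 1)
    cum <- matrix(0, nlev, n)
    for (i in seq_len(n)) {
      left[ys[i], 1] <- left[ys[i], 1] + 1
      cum[, i] <- left[, 1]
    }
    for (cut in distinct) {
      lc <- cum[, cut]; rc <- counts - lc
      gain <- g0 - (cut / n) * gini_impurity(lc) -
        ((n - cut) / n) * gini_impurity(rc)
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best <- list(f = f, thr = (xs[cut] + xs[cut + 1]) / 2)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, counts = counts))
  go_left <- X[, best$f] <= best$thr
  list(leaf = FALSE, f = best$f, thr = best$thr,
       left = grow_tree(X[go_left, , drop = FALSE], yi[go_left], nlev, mtry,
                        min_node),
       right = grow_tree(X[!go_left, , drop = FALSE], yi[!go_left], nlev,
                         mtry, min_node))
}

tree_probs <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$f] <= node$thr) node$left else node$right
  node$counts / sum(node$counts)
}

#' Random forest classifier
#'
#' CART trees on bootstrap samples with Gini splits and `floor(sqrt(p))`
#' features tried per node; 100 trees by default. Class scores are the mean
#' leaf class-vote fractions over trees.
#'
#' @param X numeric matrix (samples x features)
#' @param y class labels
#' @param n_trees number of trees (default 100)
#' @param mtry features per split (default `floor(sqrt(p))`, at least 1)
#' @param seed integer seed
#' @return object of class `random_forest`
#' @export
rf_train <- function(X, y, n_trees = 100, mtry = NULL, seed = 0L) {
  y <- as.factor(y)
  lv <- levels(y)
  yi <- as.integer(y)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(derive_seed(seed, 888L), {
    lapply(seq_len(n_trees), function(b) {
      idx <- sample.int(nrow(X), replace = TRUE)
      grow_tree(X[idx, , drop = FALSE], yi[idx], length(lv), mtry)
    })
  })
  structure(list(trees = trees, levels = lv), class = "random_forest")
}

#' @rdname rf_train
#' @param object fitted forest
#' @param newdata matrix of rows to score
#' @param ... unused
#' @export
predict.random_forest <- function(object, newdata, ...) {
  S <- t(apply(newdata, 1, function(x) {
    rowMeans(vapply(object$trees, tree_probs, numeric(length(object$levels)),
                    x = x))
  }))
  if (nrow(newdata) == 1) S <- matrix(S, 1)
  colnames(S) <- object$levels
  cls <- factor(object$levels[max.col(S, ties.method = "first")],
                levels = object$levels)
  list(class = cls, scores = S)
}
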
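# Cross-validated evaluation: fold construction, per-fold standardization
# and (optionally nested) feature selection, metric aggregation over pooled
# fold-wise predictions.

make_folds <- function(y, cv = c("loocv", "stratified_5fold"), seed = 0L) {
  cv <- match.arg(cv)
  n <- length(y)
  if (cv == "loocv") return(as.list(seq_len(n)))
  y <- as.factor(y)
  folds <- vector("list", 5)
  with_seed(derive_seed(seed, 555L), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fi <- rep(seq_len(5), length.out = length(idx))
      for (f in seq_len(5)) folds[[f]] <- c(folds[[f]], idx[fi == f])
    }
  })
  lapply(folds, sort)
}

# Mann-Whitney AUC from pooled scores
auc_score <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

classification_metrics <- function(truth, predicted, scores) {
  lv <- levels(truth)
  cm <- table(truth = truth, predicted = factor(predicted, levels = lv))
  acc <- sum(diag(cm)) / sum(cm)
  f1 <- vapply(lv, function(cl) {
    tp <- cm[cl, cl]; fp <- sum(cm[, cl]) - tp; fn <- sum(cm[cl, ]) - tp
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  auc <- vapply(lv, function(cl) auc_score(scores[, cl], truth == cl),
                numeric(1))
  list(accuracy = acc, macro_f1 = mean(f1), f1 = f1, auc = auc,
       confusion = unclass(cm))
}

#' Cross-validated classification of consciousness states
#'
#' Runs the full per-fold protocol: standardize on the training rows, select
#' features (nested by default; with `nested_selection = FALSE`, the
#' "paper-mode" global selection is performed once on the full standardized
#' table before CV), fit the model, score the held-out rows. Accuracy,
#' per-class and macro F1, the confusion matrix and per-class one-vs-rest
#' AUCs are computed from the pooled fold-wise predictions.
#'
#' @param features a [build_features()] table (or any data.frame with
#'   `subject`, `condition` and numeric feature columns); `condition` is the
#'   class label
#' @param model `"linear_svm"` or `"random_forest"`
#' @param cv `"loocv"` or `"stratified_5fold"`
#' @param nested_selection run NCA+MRMR selection inside each training fold
#' @param select perform feature selection at all (FALSE = use all columns)
#' @param top_n features kept by the composite selection
#' @param seed integer seed (folds, SVM coordinate order, forest bootstrap)
#' @param n_trees forest size when `model = "random_forest"`
#' @return object of class `classification_report`: metrics, `confusion`,
#'   `predictions` (fold-wise log), `selected` (per-fold or global feature
#'   sets), `cv_scheme`, `model`
#' @export
evaluate <- function(features, model = c("linear_svm", "random_forest"),
                     cv = c("loocv", "stratified_5fold"),
                     nested_selection = TRUE, select = TRUE, top_n = 10,
                     seed = 0L, n_trees = 100) {
  model <- match.arg(model)
  cv <- match.arg(cv)
  X <- feature_matrix(features)
  y <- as.factor(features$condition)
  assert_that(nlevels(y) >= 2, "need at least two classes")
  assert_that(min(table(y)) >= 2, "need at least two samples per class")
  folds <- make_folds(y, cv, seed)
  global_sel <- NULL
  if (select && !nested_selection) {
    fit0 <- standardize_fit(X)
    Z0 <- standardize_apply(X, fit0)
    global_sel <- composite_select(nca_weights(Z0, y),
                                   mrmr_scores(Z0, y), top_n)$selected
  }
  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
  scores <- matrix(NA_real_, nrow(X), nlevels(y),
                   dimnames = list(NULL, levels(y)))
  fold_of <- integer(nrow(X))
  sel_log <- list()
  folds <- Filter(length, folds)
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(nrow(X)), te)
    assert_that(nlevels(droplevels(y[tr])) == nlevels(y),
                "a training fold lost a class; use stratified CV")
    fit <- standardize_fit(X[tr, , drop = FALSE])
    Ztr <- standardize_apply(X[tr, , drop = FALSE], fit)
    Zte <- standardize_apply(X[te, , drop = FALSE], fit)
    sel <- if (!select) colnames(X)
           else if (nested_selection)
             composite_select(nca_weights(Ztr, y[tr]),
                              mrmr_scores(Ztr, y[tr]), top_n)$selected
           else global_sel
    sel_log[[f]] <- sel
    Ztr <- Ztr[, sel, drop = FALSE]; Zte <- Zte[, sel, drop = FALSE]
    fitm <- if (model == "linear_svm")
      svm_train(Ztr, y[tr], seed = derive_seed(seed, 7L, f))
    else
      rf_train(Ztr, y[tr], n_trees = n_trees,
               seed = derive_seed(seed, 7L, f))
    pr <- stats::predict(fitm, Zte)
    pred[te] <- pr$class
    scores[te, ] <- pr$scores
    fold_of[te] <- f
  }
  met <- classification_metrics(y, pred, scores)
  structure(c(met,
              list(predictions = data.frame(fold = fold_of,
                                            truth = y, predicted = pred),
                   scores = scores,
                   selected = if (select && !nested_selection) global_sel
                              else sel_log,
                   cv_scheme = cv, model = model, seed = seed)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report: %s / %s, accuracy=%.3f, macro_f1=%.3f>\n",
              x$model, x$cv_scheme, x$accuracy, x$macro_f1))
  print(round(rbind(F1 = x$f1, AUC = x$auc), 3))
  invisible(x)
}
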
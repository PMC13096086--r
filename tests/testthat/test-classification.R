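# classification module: feature tables, standardization, NCA, MRMR,
# composite selection, cross-validated evaluation.

fake_metrics <- function(n_subj = 21, bands = c("alpha"),
                         conds = c("wake", "LOC", "ROC"), K = 7, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("S%02d", 1:n_subj),
                      condition = conds, band = bands,
                      class = LETTERS[1:K], stringsAsFactors = FALSE)
  grid$duration_ms <- rnorm(nrow(grid), 80, 10) +
    ifelse(grid$condition == "LOC", 40, 0)
  grid$occurrence_per_s <- rnorm(nrow(grid), 3, 0.5)
  grid$coverage_fraction <- runif(nrow(grid), 0.1, 0.2)
  grid$iev <- runif(nrow(grid), 0.05, 0.15)
  grid
}

test_that("build_features produces the documented column counts", {
  m1 <- fake_metrics(bands = "alpha")
  f1 <- build_features(m1, "alpha")
  expect_equal(ncol(f1) - 2, 28)                    # 7 classes x 4 params
  expect_equal(nrow(f1), 63)                        # 21 x 3
  m5 <- do.call(rbind, lapply(c("delta", "theta", "alpha", "beta", "gamma"),
                              function(b) fake_metrics(bands = b)))
  f5 <- build_features(m5, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(ncol(f5) - 2, 140)
  m6 <- rbind(m5, fake_metrics(bands = "broadband"))
  f6 <- build_features(m6, c("broadband", "delta", "theta", "alpha", "beta",
                             "gamma"))
  expect_equal(ncol(f6) - 2, 168)
  expect_true(all(grepl("^\\w+\\.[A-G]\\.(duration|occurrence|coverage|ev)$",
                        setdiff(names(f6), c("subject", "condition")))))
  # missing class duration imputed 0 and flagged
  m1miss <- m1
  m1miss$duration_ms[1] <- NA
  f1m <- build_features(m1miss, "alpha")
  expect_length(attr(f1m, "imputed"), 1)
})

test_that("standardization fits on train and transforms test consistently", {
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50)
  X[, 4] <- 2                                        # constant column
  fit <- standardize_fit(X)
  Z <- standardize_apply(X, fit)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z[, 1:3], 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(Z[, 4] == 0))
  expect_true(fit$constant[4])
  # inverse transform is the identity
  back <- sweep(sweep(Z, 2, fit$sd, "*"), 2, fit$mean, "+")
  expect_equal(back, X, tolerance = 1e-12)
  # test rows do not alter train statistics
  Xtest <- X + 100
  fit2 <- standardize_fit(X)
  expect_identical(fit$mean, fit2$mean)
  Zt <- standardize_apply(Xtest, fit)
  expect_equal(colMeans(Zt)[1:3] > 50, rep(TRUE, 3), ignore_attr = TRUE)
})

test_that("NCA upweights discriminative features and shrinks under penalty", {
  seps <- replicate(20, {
    y <- rep(c("a", "b"), each = 20)
    X <- cbind(signal = rnorm(40) + ifelse(y == "a", 0, 5),
               noise = rnorm(40))
    Z <- standardize_apply(X, standardize_fit(X))
    w <- nca_weights(Z, y)
    w["noise"] / w["signal"]
  })
  expect_lt(median(seps), 0.10)
  # duplicated informative feature: both keep positive weight
  set.seed(5)
  y <- rep(c("a", "b"), each = 15)
  s <- rnorm(30) + ifelse(y == "a", 0, 4)
  X <- cbind(s1 = s, s2 = s)
  w <- nca_weights(standardize_apply(X, standardize_fit(X)), y)
  expect_true(all(w > 1e-4))
  # heavy regularization drives all weights to ~0
  wl <- nca_weights(standardize_apply(X, standardize_fit(X)), y, lambda = 1e4)
  expect_lt(max(wl), 1e-4)
  expect_error(nca_weights(X, rep("a", 30)), "two classes")
})

test_that("MRMR ranks label-coding features first and punishes duplicates", {
  set.seed(7)
  y <- rep(c("a", "b", "c"), each = 20)
  code <- as.integer(factor(y)) + rnorm(60, sd = 1e-6)
  X <- cbind(code = code, dup = code, noise = runif(60))
  sc <- mrmr_scores(X, y)
  ord <- attr(sc, "order")
  expect_equal(ord[1], "code")
  # duplicate of a selected feature scores no better than its relevance drop
  expect_lt(sc["dup"], 0)
  # independent noise has ~zero MI beyond binning bias (permutation baseline)
  perm_mi <- replicate(50, {
    freqstate:::discrete_mi(freqstate:::equal_freq_bins(runif(60)), sample(y))
  })
  expect_lt(abs(freqstate:::discrete_mi(freqstate:::equal_freq_bins(X[, "noise"]), y)),
            quantile(perm_mi, 0.99) + 0.05)
})

test_that("composite_select normalizes, sums, and breaks ties as documented", {
  nca <- c(a = 2, b = 4, c = 6)
  mrmr <- c(a = 0, b = 1, c = 0.5)
  out <- composite_select(nca, mrmr, top_n = 2)
  expect_equal(out$scores$nca01, c(0, 0.5, 1))
  expect_equal(out$scores$composite, c(0, 1.5, 1.5))
  # tie at the cut between b and c: NCA weight decides (c wins)
  expect_setequal(out$selected, c("c", "b"))
  expect_equal(out$selected[1], "c")
  # feature top in both lists scores 2 and is selected
  both <- composite_select(c(x = 1, y = 9), c(x = 0.1, y = 3), top_n = 1)
  expect_equal(both$scores$composite[2], 2)
  expect_equal(both$selected, "y")
  # degenerate all-equal vector contributes zeros
  z <- composite_select(c(x = 1, y = 1), c(x = 0, y = 2), top_n = 1)
  expect_equal(z$scores$composite, c(0, 1))
})

separable_features <- function(n_per = 21, seed = 3) {
  set.seed(seed)
  cond <- rep(c("wake", "LOC", "ROC"), each = n_per)
  data.frame(subject = sprintf("S%02d", rep(1:n_per, 3)),
             condition = cond,
             f1 = rnorm(3 * n_per) + 20 * (cond == "LOC"),
             f2 = rnorm(3 * n_per) + 20 * (cond == "ROC"),
             f3 = rnorm(3 * n_per),
             f4 = rnorm(3 * n_per))
}

test_that("both classifiers are perfect on separable classes under both CVs", {
  feats <- separable_features()
  for (mdl in c("linear_svm", "random_forest"))
    for (cv in c("loocv", "stratified_5fold")) {
      rep <- evaluate(feats, model = mdl, cv = cv, select = FALSE, seed = 1)
      expect_equal(rep$accuracy, 1)
      expect_equal(unname(rep$f1), rep(1, 3))
      expect_equal(unname(rep$auc), rep(1, 3))
      # confusion row sums = class counts
      expect_equal(unname(rowSums(rep$confusion)), rep(21, 3))
    }
})

test_that("evaluation is deterministic under a fixed seed", {
  feats <- separable_features(8)
  r1 <- evaluate(feats, model = "random_forest", cv = "stratified_5fold",
                 select = FALSE, seed = 11, n_trees = 25)
  r2 <- evaluate(feats, model = "random_forest", cv = "stratified_5fold",
                 select = FALSE, seed = 11, n_trees = 25)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("nested selection finds the discriminative features", {
  feats <- separable_features()
  rep <- evaluate(feats, model = "linear_svm", cv = "stratified_5fold",
                  nested_selection = TRUE, top_n = 2, seed = 2)
  expect_equal(rep$accuracy, 1)
  expect_true(all(vapply(rep$selected, function(s)
    setequal(s, c("f1", "f2")), logical(1))))
  # paper-mode: one global selection reused across folds
  repg <- evaluate(feats, model = "linear_svm", cv = "stratified_5fold",
                   nested_selection = FALSE, top_n = 2, seed = 2)
  expect_setequal(repg$selected, c("f1", "f2"))
  expect_equal(repg$accuracy, 1)
})

test_that("report metrics are recomputable from the prediction log", {
  feats <- separable_features(8)
  feats$f1 <- feats$f1 / 40 + rnorm(24)     # make it imperfect
  rep <- evaluate(feats, model = "linear_svm", cv = "loocv", select = FALSE,
                  seed = 4)
  acc <- mean(rep$predictions$truth == rep$predictions$predicted)
  expect_equal(rep$accuracy, acc)
  cm <- table(rep$predictions$truth, rep$predictions$predicted)
  expect_equal(unclass(cm), rep$confusion, ignore_attr = TRUE)
})

test_that("adding an informative band cannot hurt a band-limited model
           (scaled directional check)", {
  # band-specific information: alpha metrics separate the conditions,
  # delta metrics are pure noise
  set.seed(12)
  mk <- function(b, effect) {
    g <- expand.grid(subject = sprintf("S%02d", 1:15),
                     condition = c("wake", "LOC", "ROC"), band = b,
                     class = LETTERS[1:4], stringsAsFactors = FALSE)
    g$duration_ms <- rnorm(nrow(g), 80, 5) +
      40 * effect * (g$condition == "LOC")
    g$occurrence_per_s <- rnorm(nrow(g), 3, 0.5) +
      4 * effect * (g$condition == "ROC")
    g$coverage_fraction <- runif(nrow(g), 0.1, 0.3)
    g$iev <- runif(nrow(g), 0.05, 0.2)
    g
  }
  metrics <- rbind(mk("alpha", 1), mk("delta", 0))
  acc <- function(bands) {
    f <- build_features(metrics, bands)
    evaluate(f, model = "linear_svm", cv = "stratified_5fold",
             nested_selection = TRUE, top_n = 5, seed = 3)$accuracy
  }
  acc_delta <- acc("delta")
  acc_both <- acc(c("alpha", "delta"))
  expect_gte(acc_both, acc_delta)
  expect_gt(acc_both, 0.9)
})
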
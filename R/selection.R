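# Hybrid feature selection: diagonal neighborhood component analysis (NCA)
# and greedy minimum-redundancy maximum-relevance (MRMR), combined by
# min-max-normalized composite score.

#' Diagonal NCA feature weights
#'
#' Learns one non-negative weight per feature by maximizing the expected
#' leave-one-out accuracy of a stochastic nearest neighbour classifier:
#' `p_i = sum_{j in class(i)} p_ij` with
#' `p_ij = exp(-d_w(x_i, x_j)) / sum_{k != i} exp(-d_w(x_i, x_k))` and
#' `d_w = sum_f w_f^2 (x_if - x_jf)^2`, minus an L2 penalty
#' `lambda * sum w_f^2`. Optimized by L-BFGS from `w = 1` with an analytic
#' gradient and a per-row log-sum-exp shift for numerical stability; the
#' reported importance is `w_f^2`.
#'
#' @param X standardized numeric matrix (samples x features)
#' @param y class labels (factor or vector), at least two classes
#' @param lambda regularization (default `1/n`, the conventional scaling)
#' @param seed unused randomness guard (the optimization is deterministic
#'   from `w = 1`; kept for interface stability)
#' @param maxit L-BFGS iteration cap
#' @return named vector of importances (`w^2`)
#' @export
nca_weights <- function(X, y, lambda = NULL, seed = 0L, maxit = 200) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  assert_that(nlevels(droplevels(y)) >= 2, "NCA needs at least two classes")
  lambda <- lambda %||% (1 / n)
  same <- outer(y, y, "==") & !diag(TRUE, n)
  # squared differences, flattened n*n x p
  D2 <- matrix(0, n * n, p)
  for (f in seq_len(p)) D2[, f] <- as.vector(outer(X[, f], X[, f], "-")^2)

  objective <- function(w) {
    d <- matrix(D2 %*% (w^2), n, n)
    diag(d) <- Inf
    dmin <- apply(d, 1, min)
    dmin[!is.finite(dmin)] <- 0
    E <- exp(-(d - dmin))       # row-shifted, diag exp(-Inf)=0
    rs <- rowSums(E)
    P <- E / ifelse(rs > 0, rs, 1)
    pi_i <- rowSums(P * same)
    f <- sum(pi_i) - lambda * sum(w^2)
    # gradient
    W <- P * pi_i - P * same
    g <- 2 * w * drop(crossprod(D2, as.vector(W))) - 2 * lambda * w
    list(value = -f, gradient = -g)
  }
  env <- new.env(); env$g <- NULL
  fn <- function(w) { r <- objective(w); env$g <- r$gradient; r$value }
  gr <- function(w) env$g
  opt <- stats::optim(rep(1, p), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  w2 <- opt$par^2
  names(w2) <- colnames(X) %||% paste0("F", seq_len(p))
  w2
}

# mutual information (nats) between two discrete codes
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

equal_freq_bins <- function(x, bins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Greedy MRMR feature scores
#'
#' Mutual-information difference (MID) scheme: continuous features are
#' discretized into 10 equal-frequency bins; the first feature selected
#' maximizes relevance `MI(f; y)`, and each subsequent pick maximizes
#' `MI(f; y) - mean_s MI(f; s)` over the already-selected set `s`. The score
#' recorded for each feature is its criterion value at selection time, so
#' scores preserve the greedy rank order.
#'
#' @param X numeric matrix (samples x features)
#' @param y class labels
#' @param bins discretization bins (default 10, equal frequency)
#' @return named vector of scores in original column order, with attribute
#'   `order` giving the greedy ranking
#' @export
mrmr_scores <- function(X, y, bins = 10) {
  X <- as.matrix(X)
  p <- ncol(X)
  disc <- lapply(seq_len(p), function(f) equal_freq_bins(X[, f], bins))
  rel <- vapply(disc, function(d) discrete_mi(d, y), numeric(1))
  selected <- integer(0)
  scores <- rep(NA_real_, p)
  red_sum <- rep(0, p)
  remaining <- seq_len(p)
  while (length(remaining) > 0) {
    crit <- if (length(selected) == 0) rel[remaining]
            else rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]
    scores[pick] <- max(crit)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0) {
      mi_new <- vapply(remaining, function(f) discrete_mi(disc[[f]], disc[[pick]]),
                       numeric(1))
      red_sum[remaining] <- red_sum[remaining] + mi_new
    }
  }
  names(scores) <- colnames(X) %||% paste0("F", seq_len(p))
  attr(scores, "order") <- names(scores)[selected]
  scores
}

minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))  # documented convention
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Composite NCA + MRMR selection
#'
#' Min-max normalizes each score vector to \[0, 1\], sums them into a
#' composite in \[0, 2\], and selects the top `top_n` features. Ties at the
#' cut are broken by NCA weight, then lexicographic feature name, so the
#' selection is deterministic.
#'
#' @param nca named NCA importances ([nca_weights()])
#' @param mrmr named MRMR scores ([mrmr_scores()])
#' @param top_n features to keep (default 10)
#' @return object of class `selection_result`: data.frame `scores`
#'   (feature, nca, mrmr, nca01, mrmr01, composite) and `selected` names
#' @export
composite_select <- function(nca, mrmr, top_n = 10) {
  assert_that(length(nca) == length(mrmr) &&
                setequal(names(nca), names(mrmr)),
              "NCA and MRMR must score the same feature set")
  mrmr <- mrmr[names(nca)]
  comp <- minmax01(nca) + minmax01(unname(mrmr))
  ord <- order(-comp, -nca, names(nca))
  top_n <- min(top_n, length(comp))
  sel <- names(nca)[ord[seq_len(top_n)]]
  structure(list(scores = data.frame(feature = names(nca),
                                     nca = unname(nca),
                                     mrmr = unname(mrmr),
                                     nca01 = minmax01(nca),
                                     mrmr01 = minmax01(unname(mrmr)),
                                     composite = comp,
                                     row.names = NULL),
                 selected = sel),
            class = "selection_result")
}
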
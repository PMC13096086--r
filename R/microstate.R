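# Microstate core: GFP, GFP-peak extraction, polarity-invariant modified
# k-means, global explained variance, the predictive-residual cross-validation
# criterion, and the k = 2..8 model scan.

#' Global field power
#'
#' GFP(t) is the population standard deviation (divisor C) of the scalp
#' potential across channels at each sample. Input should be
#' average-referenced; the instantaneous channel mean is subtracted
#' regardless, so the value is reference-robust.
#'
#' @param recording an [eeg_recording()] with >= 2 channels
#' @return object of class `gfp_series`: list with `values` (microvolts) and
#'   `peak_indices`
#' @export
compute_gfp <- function(recording) {
  X <- recording$data
  assert_that(nrow(X) >= 2, "GFP needs >= 2 channels")
  Xc <- sweep(X, 2, colMeans(X))
  values <- sqrt(colMeans(Xc^2))
  structure(list(values = values, peak_indices = detect_peaks_values(values),
                 rate = recording$rate),
            class = "gfp_series")
}

detect_peaks_values <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- 2:(n - 1)
  which(v[idx] > v[idx - 1] & v[idx] >= v[idx + 1]) + 1L
}

#' Local maxima of a GFP series
#'
#' A peak is any interior sample strictly greater than its left neighbour and
#' greater-or-equal to its right neighbour, so the first sample of a plateau
#' is the peak. No height or minimum-distance threshold is applied.
#'
#' @param gfp a [compute_gfp()] result (or numeric vector)
#' @return integer vector of peak sample indices
#' @export
detect_peaks <- function(gfp) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  detect_peaks_values(v)
}

# columns of X centered and L2-normalized; zero columns left as zero
normalize_columns <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  nz <- nrm > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2, nrm[nz], "/")
  X
}

# first left singular vector of a channels x n matrix
dominant_map <- function(M) {
  if (ncol(M) == 1) return(normalize_map(drop(M)))
  s <- svd(M, nu = 1, nv = 0)
  normalize_map(drop(s$u))
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Clusters GFP-peak topographies ignoring polarity: assignment maximizes the
#' squared spatial correlation with the class map (ties -> lowest class
#' index), and each class map is updated to the dominant eigenvector of its
#' members' outer-product sum. Because the raw (unnormalized) maps enter the
#' update, the eigenvector maximizes the GFP^2-weighted explained variance of
#' the cluster, making every iteration monotone in GEV. The best of
#' `n_restarts` random initializations (by GEV) is returned; restart r is
#' seeded deterministically from `seed` and r.
#'
#' @param peak_maps channels x n matrix of topographies (microvolts) at GFP
#'   peaks
#' @param K number of classes (K <= n maps)
#' @param n_restarts random restarts (default 20)
#' @param max_iter iteration cap per restart (default 300)
#' @param tol convergence threshold on the relative GEV change (default 1e-7)
#' @param seed base integer seed
#' @param gfp optional GFP values at the peaks (defaults to the maps' own
#'   spatial SD) used for the GEV weighting
#' @return object of class `microstate_model`: `maps` (channels x K,
#'   unit-norm), `K`, `gev_total`, `ev_per_class`, `cv_value`, `assignment`
#' @export
modified_kmeans <- function(peak_maps, K, n_restarts = 20, max_iter = 300,
                            tol = 1e-7, seed = 0L, gfp = NULL) {
  peak_maps <- as.matrix(peak_maps)
  n <- ncol(peak_maps); C <- nrow(peak_maps)
  assert_that(K >= 1 && K <= n, "need K <= number of peak maps")
  if (is.null(gfp)) gfp <- apply(peak_maps, 2, function(v) stats::sd(v) * sqrt((C - 1) / C))
  V <- normalize_columns(peak_maps)
  W <- sweep(V, 2, gfp, "*")   # gfp-weighted unit maps: eigen update on these
  g2 <- gfp^2
  sum_g2 <- sum(g2)
  assert_that(sum_g2 > 0, "all-zero GFP: GEV undefined")

  run_once <- function(rseed, init = NULL) {
    with_seed(rseed, {
      A <- V[, init %||% sample.int(n, K), drop = FALSE]
      gev_old <- -Inf; L <- NULL
      for (it in seq_len(max_iter)) {
        R <- crossprod(A, V)                      # K x n correlations
        R2 <- R^2
        L <- max.col(t(R2), ties.method = "first")
        # re-seed empty clusters from the worst-fit map
        best <- R2[cbind(L, seq_len(n))]
        for (k in seq_len(K)) {
          if (!any(L == k)) {
            w <- which.min(best)
            A[, k] <- V[, w]
            L[w] <- k
            best[w] <- 1
          }
        }
        for (k in seq_len(K)) {
          idx <- which(L == k)
          if (length(idx)) A[, k] <- dominant_map(W[, idx, drop = FALSE])
        }
        R <- crossprod(A, V); R2 <- R^2
        L <- max.col(t(R2), ties.method = "first")
        gev <- sum(g2 * R2[cbind(L, seq_len(n))]) / sum_g2
        if (is.finite(gev_old) && abs(gev - gev_old) <= tol * max(gev_old, 1e-12))
          break
        gev_old <- gev
      }
      list(maps = A, assignment = L, gev = gev)
    })
  }

  # tiny instances: the K-subset initialization space is smaller than a few
  # restart budgets, so cover it exhaustively instead of sampling (guarantees
  # the global Lloyd basin is visited whenever any subset init reaches it)
  n_subsets <- suppressWarnings(choose(n, K))
  inits <- if (is.finite(n_subsets) && n_subsets <= max(3 * n_restarts, 60))
    utils::combn(n, K, simplify = FALSE) else NULL
  best <- NULL
  for (r in seq_along(inits %||% seq_len(n_restarts))) {
    fit <- run_once(derive_seed(seed, 300L, r), init = inits[[r]])
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  ev <- gev_breakdown(best$maps, V, g2, best$assignment)
  structure(list(K = K, maps = best$maps, assignment = best$assignment,
                 gev_total = ev$gev_total, ev_per_class = ev$ev_per_class,
                 cv_value = cv_criterion_raw(best$maps, peak_maps,
                                             best$assignment),
                 labels = colnames(best$maps) %||% paste0("M", seq_len(K)),
                 level = "individual", band = NULL),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model: K=%d, GEV=%.3f, CV=%.4g, level=%s%s>\n",
              x$K, x$gev_total, x$cv_value, x$level,
              if (is.null(x$band)) "" else paste0(", band=", x$band)))
  invisible(x)
}

gev_breakdown <- function(A, V, g2, L) {
  R2 <- crossprod(A, V)^2
  num <- g2 * R2[cbind(L, seq_len(ncol(V)))]
  ev <- vapply(seq_len(ncol(A)), function(k) sum(num[L == k]), numeric(1))
  ev <- ev / sum(g2)
  list(gev_total = sum(ev), ev_per_class = ev)
}

#' Global explained variance of a microstate model
#'
#' GEV is the GFP^2-weighted mean squared spatial correlation between each
#' peak topography and its assigned class map:
#' `sum_t GFP_t^2 r^2(a_L(t), v_t) / sum_t GFP_t^2`. The per-class vector
#' partitions the same numerator by assigned class, so it sums exactly to
#' the total.
#'
#' @param model a [modified_kmeans()] model (its maps and assignment are used
#'   unless `assignment` is given)
#' @param peak_maps channels x n matrix of peak topographies
#' @param gfp_at_peaks GFP values at the peaks
#' @param assignment optional per-map class assignment (defaults to argmax
#'   squared correlation)
#' @return list with `gev_total` and `ev_per_class`
#' @export
compute_gev <- function(model, peak_maps, gfp_at_peaks, assignment = NULL) {
  V <- normalize_columns(as.matrix(peak_maps))
  g2 <- gfp_at_peaks^2
  assert_that(sum(g2) > 0, "all-zero GFP: GEV undefined")
  if (is.null(assignment)) {
    R2 <- crossprod(model$maps, V)^2
    assignment <- max.col(t(R2), ties.method = "first")
  }
  gev_breakdown(model$maps, V, g2, assignment)
}

cv_criterion_raw <- function(A, peak_maps, L) {
  C <- nrow(peak_maps); n <- ncol(peak_maps); K <- ncol(A)
  if (C - 1 <= K) return(NA_real_)
  Vc <- sweep(peak_maps, 2, colMeans(peak_maps))
  tot <- colSums(Vc^2)
  proj <- colSums(A[, L, drop = FALSE] * Vc)^2
  sigma2 <- sum(tot - proj) / (n * (C - 1))
  sigma2 * ((C - 1) / (C - 1 - K))^2
}

#' Predictive-residual cross-validation criterion
#'
#' The standard modified-k-means model-order criterion:
#' `CV = sigma^2 * ((C-1)/(C-1-K))^2` with
#' `sigma^2 = sum_t (v_t'v_t - (a_L(t)'v_t)^2) / (T (C-1))`, where `a` are the
#' unit-norm class maps and `C` the channel count. Lower is better; the
#' penalty factor grows with K.
#'
#' @param model a `microstate_model`
#' @param peak_maps channels x n matrix of peak topographies (microvolts)
#' @param assignment optional assignment override
#' @return the criterion value (microvolt^2)
#' @export
cv_criterion <- function(model, peak_maps, assignment = NULL) {
  peak_maps <- as.matrix(peak_maps)
  assert_that(nrow(peak_maps) - 1 > model$K,
              "CV criterion requires K < channels - 1")
  V <- normalize_columns(peak_maps)
  if (is.null(assignment)) {
    R2 <- crossprod(model$maps, V)^2
    assignment <- max.col(t(R2), ties.method = "first")
  }
  cv_criterion_raw(model$maps, peak_maps, assignment)
}

#' Scan the number of microstate classes
#'
#' Fits [modified_kmeans()] for each k in `k_range` under a shared restart
#' protocol and reports GEV and the CV criterion per k. `chosen_k` is the
#' configured `fixed_k` by default (the dual-criterion elbow is reported, not
#' imposed); with `method = "elbow"` the k maximizing the second difference
#' of GEV is chosen.
#'
#' @param peak_maps channels x n peak topographies
#' @param k_range candidate class counts (default 2:8)
#' @param fixed_k the k returned as `chosen_k` under `method = "fixed"`
#'   (default 7)
#' @param method `"fixed"` or `"elbow"`
#' @param gfp optional GFP at peaks
#' @inheritParams modified_kmeans
#' @return object of class `kscan_result`: data.frame `scan` (k, gev, cv),
#'   `chosen_k`, and the fitted `models`
#' @export
scan_k <- function(peak_maps, k_range = 2:8, n_restarts = 20, max_iter = 300,
                   tol = 1e-7, seed = 0L, fixed_k = 7,
                   method = c("fixed", "elbow"), gfp = NULL) {
  method <- match.arg(method)
  models <- lapply(k_range, function(k)
    modified_kmeans(peak_maps, k, n_restarts = n_restarts,
                    max_iter = max_iter, tol = tol, seed = seed, gfp = gfp))
  gev <- vapply(models, `[[`, numeric(1), "gev_total")
  cv <- vapply(models, `[[`, numeric(1), "cv_value")
  chosen <- if (method == "fixed") {
    assert_that(fixed_k %in% k_range, "fixed_k must be inside k_range")
    fixed_k
  } else if (length(k_range) >= 3) {
    d2 <- diff(diff(gev))
    k_range[which.min(d2) + 1L]   # most negative curvature = elbow
  } else k_range[which.max(gev)]
  structure(list(scan = data.frame(k = k_range, gev = gev, cv = cv),
                 chosen_k = chosen, models = stats::setNames(models, k_range)),
            class = "kscan_result")
}
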
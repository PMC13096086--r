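# Shared fixtures and independent oracles (brute force / first-principles
# arithmetic, deliberately separate from the package's code paths).

tiny_layout <- function(n = 8, seed = 1) make_layout(n, seed)

# first-principles GEV: explicit loop over peaks, Pearson correlation via cor()
oracle_gev <- function(maps, peak_maps, gfp, assignment) {
  num <- 0
  for (t in seq_len(ncol(peak_maps))) {
    r <- stats::cor(maps[, assignment[t]], peak_maps[, t])
    num <- num + gfp[t]^2 * r^2
  }
  num / sum(gfp^2)
}

# exhaustive modified-k-means optimum for K = 2: enumerate all label
# assignments, refit optimal maps per cluster (dominant eigenvector), take
# the best GEV over assignments
oracle_kmeans_k2 <- function(peak_maps, gfp) {
  n <- ncol(peak_maps)
  V <- apply(peak_maps, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  Wm <- sweep(V, 2, gfp, "*")
  g2 <- gfp^2
  best <- -Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(n)] + 1L
    if (length(unique(lab)) < 2) next
    gev <- 0
    for (k in 1:2) {
      M <- Wm[, lab == k, drop = FALSE]
      ev <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1]
      gev <- gev + sum(drop(crossprod(ev, M))^2)
    }
    best <- max(best, gev / sum(g2))
  }
  best
}

# brute-force optimal one-to-one template assignment by total |r|
oracle_sort_assignment <- function(maps, templates) {
  K <- ncol(maps)
  idx <- seq_len(ncol(templates))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_s <- -Inf
  for (p in perms(idx)) {
    sel <- p[seq_len(K)]
    s <- sum(vapply(seq_len(K), function(k)
      abs(stats::cor(maps[, k], templates[, sel[k]])), numeric(1)))
    if (s > best_s) { best_s <- s; best <- sel }
  }
  best
}

# small synthetic recording with known labels, for backfit tests
make_toy_world <- function(n_ch = 12, K = 3, duration_s = 60, snr = Inf,
                           seed = 7, dwell = 80) {
  lay <- make_layout(n_ch, seed)
  tpl <- make_templates(K, lay, seed + 1)
  spec <- synthetic_spec(n_subjects = 1, conditions = "wake",
                         n_channels = n_ch, K = K,
                         duration_s = c(wake = duration_s),
                         dwell_mean_ms = c(wake = dwell),
                         snr = snr, between_subject_sd = 0, seed = seed)
  labels <- sample_state_sequence(spec, "wake", seed + 2)
  rec <- synthesize_recording(spec, labels, tpl, seed + 3, "wake",
                              layout = lay)
  list(layout = lay, templates = tpl, spec = spec, labels = labels,
       recording = rec)
}

model_from_maps <- function(maps) {
  structure(list(K = ncol(maps), maps = maps, assignment = NULL,
                 gev_total = NA_real_, ev_per_class = rep(NA_real_, ncol(maps)),
                 cv_value = NA_real_,
                 labels = colnames(maps) %||% paste0("M", seq_len(ncol(maps))),
                 level = "grand", band = NULL),
            class = "microstate_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
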
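# microstate_core module: GFP, peaks, modified k-means, GEV, CV, k-scan.

test_that("compute_gfp is the population SD across channels", {
  lay <- make_layout(2, 1)
  rec <- eeg_recording(rbind(c(1, 2, 0), c(-1, 2, 0)), 250, lay)
  g <- compute_gfp(rec)
  expect_equal(g$values, c(1, 0, 0))           # [+1,-1] => 1 with divisor C
  # uniform topography has zero GFP; scaling is homogeneous
  rec4 <- eeg_recording(matrix(rnorm(40), 4), 250, make_layout(4, 1))
  expect_equal(compute_gfp(eeg_recording(3 * rec4$data, 250, rec4$layout))$values,
               3 * compute_gfp(rec4)$values, tolerance = 1e-12)
})

test_that("detect_peaks finds strict maxima with the plateau tie rule", {
  expect_length(detect_peaks(1:10), 0)                  # monotone ramp
  expect_equal(detect_peaks(c(0, 1, 1, 0)), 2L)         # first plateau sample
  fs <- 250
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  v <- 1 + 0.5 * sin(2 * pi * 10 * t)
  npk <- length(detect_peaks(v))
  expect_true(abs(npk - 10) <= 1)
})

test_that("modified k-means recovers separable structure exactly", {
  lay <- make_layout(16, 3)
  tpl <- make_templates(2, lay, 4)
  tpl[, 2] <- tpl[, 2] - sum(tpl[, 2] * tpl[, 1]) * tpl[, 1]
  tpl[, 2] <- tpl[, 2] / sqrt(sum(tpl[, 2]^2))
  set.seed(9)
  n <- 40
  lab <- rep(1:2, each = n / 2)
  signs <- sample(c(-1, 1), n, replace = TRUE)
  amp <- runif(n, 0.5, 2)
  maps <- tpl[, lab] * rep(signs * amp, each = 16)
  m <- modified_kmeans(maps, 2, n_restarts = 5, seed = 1)
  expect_gt(m$gev_total, 1 - 1e-9)
  r <- abs(crossprod(m$maps, tpl))
  expect_gt(max(r[, 1]), 1 - 1e-9)
  expect_gt(max(r[, 2]), 1 - 1e-9)
  expect_equal(sum(m$ev_per_class), m$gev_total, tolerance = 1e-12)
  expect_error(modified_kmeans(maps, 41, seed = 1), "K")
})

test_that("K = 1 returns the dominant eigenvector of the maps", {
  set.seed(2)
  maps <- matrix(rnorm(6 * 20), 6)
  m <- modified_kmeans(maps, 1, n_restarts = 2, seed = 1)
  Vc <- sweep(maps, 2, colMeans(maps))       # raw update is GFP-weighted
  pc1 <- eigen(tcrossprod(Vc), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(cor(m$maps[, 1], pc1)), 1 - 1e-9)
})

test_that("k-means GEV equals the exhaustive optimum (brute-force oracle)", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(6:9, 1)
    maps <- matrix(rnorm(4 * n), 4)
    gfp <- apply(maps, 2, function(v) sd(v) * sqrt(3 / 4))
    m <- modified_kmeans(maps, 2, n_restarts = 20, seed = i)
    expect_equal(m$gev_total, oracle_kmeans_k2(maps, gfp), tolerance = 1e-9)
  }
})

test_that("GEV matches first-principles arithmetic and its edge cases", {
  lay <- make_layout(6, 5)
  tpl <- make_templates(2, lay, 6)
  set.seed(4)
  peaks <- matrix(rnorm(6 * 5), 6)
  peaks <- sweep(peaks, 2, colMeans(peaks))
  gfp <- sqrt(colMeans(peaks^2))
  m <- model_from_maps(tpl)
  g <- compute_gev(m, peaks, gfp)
  R2 <- crossprod(tpl, apply(peaks, 2, function(v) v / sqrt(sum(v^2))))^2
  assignment <- apply(R2, 2, which.max)
  expect_equal(g$gev_total, oracle_gev(tpl, peaks, gfp, assignment),
               tolerance = 1e-12)
  expect_equal(sum(g$ev_per_class), g$gev_total, tolerance = 1e-14)
  # collinear peaks: GEV = 1; orthogonal maps: GEV = 0
  col_peaks <- tpl[, c(1, 2, 1)] * rep(c(2, 3, 4), each = 6)
  expect_equal(compute_gev(m, col_peaks, sqrt(colMeans(col_peaks^2)))$gev_total,
               1, tolerance = 1e-12)
  orth <- qr.Q(qr(cbind(tpl, rnorm(6))))[, 3, drop = FALSE]
  orth <- orth - mean(orth)
  g0 <- compute_gev(m, orth, sqrt(mean(orth^2)))
  expect_lt(g0$gev_total, 0.3)
})

test_that("CV criterion matches hand evaluation and penalizes K", {
  set.seed(8)
  peaks <- matrix(rnorm(5 * 4), 5)
  peaks <- sweep(peaks, 2, colMeans(peaks))
  lay5 <- make_layout(5, 1)
  tpl <- make_templates(2, lay5, 2)
  m <- model_from_maps(tpl)
  got <- cv_criterion(m, peaks)
  # first-principles evaluation
  V <- apply(peaks, 2, function(v) v / sqrt(sum(v^2)))
  assignment <- apply(crossprod(tpl, V)^2, 2, which.max)
  s2 <- 0
  for (t in 1:4)
    s2 <- s2 + sum(peaks[, t]^2) - sum(tpl[, assignment[t]] * peaks[, t])^2
  s2 <- s2 / (4 * (5 - 1))
  expect_equal(got, s2 * ((5 - 1) / (5 - 1 - 2))^2, tolerance = 1e-12)
  # perfect fit -> CV = 0
  perfect <- tpl[, c(1, 2)] * rep(c(2, 5), each = 5)
  expect_lt(cv_criterion(m, perfect), 1e-12)
  # penalty factor increases strictly in K for fixed residual
  f <- function(K, C = 12) ((C - 1) / (C - 1 - K))^2
  expect_true(all(diff(sapply(1:8, f)) > 0))
  expect_error(cv_criterion(m, peaks[1:3, ]), "K < channels")
})

test_that("polarity and permutation invariance hold", {
  set.seed(12)
  lay <- make_layout(8, 2)
  tpl <- make_templates(3, lay, 3)
  maps <- tpl[, sample(1:3, 30, replace = TRUE)] + matrix(rnorm(8 * 30, sd = 0.2), 8)
  m1 <- modified_kmeans(maps, 3, n_restarts = 10, seed = 5)
  flip <- maps %*% diag(sample(c(-1, 1), 30, replace = TRUE))
  m2 <- modified_kmeans(flip, 3, n_restarts = 10, seed = 5)
  expect_equal(m2$gev_total, m1$gev_total, tolerance = 1e-9)
  perm <- maps[, sample(30)]
  m3 <- modified_kmeans(perm, 3, n_restarts = 10, seed = 5)
  expect_equal(m3$gev_total, m1$gev_total, tolerance = 1e-6)
})

test_that("scan_k reports non-decreasing GEV and honours fixed k", {
  w <- make_toy_world(n_ch = 12, K = 4, duration_s = 30, snr = 8)
  g <- compute_gfp(w$recording)
  pm <- w$recording$data[, g$peak_indices]
  ks <- scan_k(pm, k_range = 2:8, n_restarts = 5, seed = 3, fixed_k = 7,
               gfp = g$values[g$peak_indices])
  expect_equal(ks$chosen_k, 7)
  expect_true(all(diff(ks$scan$gev) > -1e-6))
  # elbow at the true K: gain from 4->5 less than half the gain from 3->4
  gev <- ks$scan$gev
  expect_lt(gev[4] - gev[3], (gev[3] - gev[2]) / 2)
  ke <- scan_k(pm, k_range = 2:8, n_restarts = 5, seed = 3, method = "elbow",
               gfp = g$values[g$peak_indices])
  expect_equal(ke$chosen_k, 4)
})
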
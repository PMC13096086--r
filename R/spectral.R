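# Multitaper spectral estimation with discrete prolate spheroidal (Slepian)
# tapers. Tapers are computed from the classic symmetric tridiagonal
# eigenproblem; concentration ratios come from the sinc-kernel quadratic form
# and weight the per-taper eigenspectra.

.dpss_cache <- new.env(parent = emptyenv())

# K unit-energy DPSS tapers of length n with time-bandwidth product nw,
# plus their concentration ratios (eigenvalues of the spectral concentration
# operator). Cached per (n, nw, K).
dpss_tapers <- function(n, nw, K) {
  key <- sprintf("%d_%g_%d", n, nw, K)
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- nw / n
  t <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off_v <- t[-1] * (n - t[-1]) / 2
  M <- diag(diag_v)
  idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  M[idx] <- off_v; M[idx[, 2:1]] <- off_v
  eg <- eigen(M, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(K), drop = FALSE]
  # unit energy; fix sign convention (positive mean, else positive first slope)
  for (k in seq_len(K)) {
    v <- tap[, k]
    s <- sum(v)
    if (abs(s) > 1e-9) { if (s < 0) v <- -v } else if (v[2] - v[1] < 0) v <- -v
    tap[, k] <- v / sqrt(sum(v^2))
  }
  # concentration ratios via the sinc kernel
  d <- outer(t, t, "-")
  S <- sin(2 * pi * W * d) / (pi * d)
  diag(S) <- 2 * W
  lam <- vapply(seq_len(K), function(k) drop(crossprod(tap[, k], S %*% tap[, k])),
                numeric(1))
  out <- list(tapers = tap, eigen = lam)
  .dpss_cache[[key]] <- out
  out
}

#' Multitaper power spectral density
#'
#' Sliding-window multitaper PSD: within each window the eigenvalue-weighted
#' average of the Slepian-tapered eigenspectra, then the mean over windows per
#' channel. Defaults encode the standard anesthesia-EEG parameterization:
#' 2-s windows with 0.5-s overlap (1.5-s hop), time-bandwidth product 3,
#' five tapers. Output is restricted to `fmin`..`fmax` (default 1-45 Hz);
#' grid spacing is `1/window_s`.
#'
#' @param recording an [eeg_recording()] (at least one window long)
#' @param window_s window length in seconds
#' @param step_s hop between window starts in seconds
#' @param time_bandwidth time-bandwidth product NW
#' @param n_tapers number of Slepian tapers
#' @param fmin,fmax retained frequency range in Hz
#' @return object of class `spectral_summary`: list with `freqs` (Hz) and
#'   `psd` (channels x freqs, microvolt^2/Hz), plus the window parameters
#' @export
multitaper_psd <- function(recording, window_s = 2, step_s = 1.5,
                           time_bandwidth = 3, n_tapers = 5,
                           fmin = 1, fmax = 45) {
  fs <- recording$rate
  nwin <- as.integer(round(window_s * fs))
  step <- as.integer(round(step_s * fs))
  n <- ncol(recording$data)
  assert_that(n >= nwin, "recording shorter than one analysis window")
  dp <- dpss_tapers(nwin, time_bandwidth, n_tapers)
  lam <- dp$eigen
  starts <- seq(1, n - nwin + 1, by = step)
  freqs <- seq(0, fs / 2, by = fs / nwin)
  keep <- which(freqs >= fmin & freqs <= fmax)
  C <- nrow(recording$data)
  acc <- matrix(0, C, length(freqs))
  for (s0 in starts) {
    seg <- recording$data[, s0:(s0 + nwin - 1), drop = FALSE]   # C x nwin
    Sw <- matrix(0, C, length(freqs))
    for (k in seq_len(n_tapers)) {
      tx <- t(seg) * dp$tapers[, k]                 # nwin x C
      X <- stats::mvfft(tx)[seq_along(freqs), , drop = FALSE]
      P <- (Mod(X)^2) / fs
      # one-sided scaling: double everything but DC and Nyquist
      dbl <- rep(2, length(freqs))
      dbl[1] <- 1
      if (nwin %% 2 == 0) dbl[length(freqs)] <- 1
      Sw <- Sw + lam[k] * t(P * dbl)
    }
    acc <- acc + Sw / sum(lam)
  }
  psd <- acc / length(starts)
  structure(list(freqs = freqs[keep],
                 psd = psd[, keep, drop = FALSE],
                 window_s = window_s, step_s = step_s,
                 time_bandwidth = time_bandwidth, n_tapers = n_tapers,
                 n_windows = length(starts), rate = fs),
            class = "spectral_summary")
}

#' Band-averaged power
#'
#' Mean PSD over the frequency bins falling inclusively inside each band
#' (a bin sitting on a shared edge, e.g. 4 Hz, contributes to both bands —
#' matching the inclusive band notation; switch by adjusting edges).
#'
#' @param summary a [multitaper_psd()] result
#' @param bands named list of [band_definition()]s
#' @return data.frame: band, channel, power (plus channel-mean rows with
#'   channel = "mean")
#' @export
band_power <- function(summary, bands) {
  rows <- lapply(bands, function(b) {
    sel <- which(summary$freqs >= b$low & summary$freqs <= b$high)
    assert_that(length(sel) > 0,
                sprintf("band %s contains no frequency bins", b$name))
    p <- rowMeans(summary$psd[, sel, drop = FALSE])
    data.frame(band = b$name,
               channel = c(seq_along(p), NA),
               power = c(p, mean(p)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize band powers to a baseline condition
#'
#' Expresses power relative to the baseline (wakefulness) value, per
#' subject x band x channel, either as `10*log10(power/baseline)` decibels
#' (default, the standard anesthesia-spectrogram convention) or as a linear
#' ratio.
#'
#' @param table tidy data.frame with columns subject, condition, band,
#'   channel, power
#' @param baseline_condition condition serving as baseline (default "wake")
#' @param scale `"db"` or `"ratio"`
#' @return the table with `power` replaced by the normalized value; baseline
#'   rows map to 0 dB (ratio 1)
#' @export
normalize_to_baseline <- function(table, baseline_condition = "wake",
                                  scale = c("db", "ratio")) {
  scale <- match.arg(scale)
  key <- function(d) paste(d$subject, d$band, d$channel, sep = "\r")
  base <- table[table$condition == baseline_condition, ]
  assert_that(nrow(base) > 0, "no baseline rows found")
  bmap <- stats::setNames(base$power, key(base))
  bp <- bmap[key(table)]
  assert_that(!anyNA(bp), "baseline missing for some subject x band x channel")
  assert_that(all(bp > 0), "zero baseline power: normalization undefined")
  ratio <- table$power / bp
  table$power <- if (scale == "db") 10 * log10(ratio) else ratio
  table
}
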
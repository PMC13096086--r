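# Synthetic EEG cohorts with known microstate ground truth. The generator
# states a world: a semi-Markov sequence of quasi-stable topographies
# (gamma dwell times, no self-transitions), each state's template scaled by a
# rectified band-limited carrier envelope, plus spatially white noise at a
# chosen SNR. It exists so every downstream stage is testable by parameter
# recovery; it does not claim to reproduce any empirical EEG distribution.

#' Specification of a synthetic cohort
#'
#' Defaults state the emulated design: 21 subjects, three conditions
#' (wake 300 s, LOC 300 s, ROC 180 s), 60 channels at 250 Hz, seven
#' templates, gamma dwell times with shape 2 around a wake mean of 80 ms,
#' LOC dwell x 1.5 (slower dynamics), ROC dwell / 1.3 (higher occurrence),
#' condition-dependent carrier bands (extra delta/alpha power under LOC),
#' SNR 4, 10% between-subject dwell jitter.
#'
#' @param n_subjects number of subjects
#' @param conditions condition names
#' @param n_channels electrodes in the generated montage
#' @param K number of ground-truth templates
#' @param rate sampling rate (Hz)
#' @param duration_s named seconds per condition
#' @param dwell_mean_ms named per-condition mean dwell (ms); scalar per
#'   condition applies to every class
#' @param dwell_shape gamma shape of the dwell distribution
#' @param carrier_bands named list (per condition) of 3-column matrices /
#'   lists of `c(low, high, amplitude)` carrier components
#' @param snr signal-to-noise power ratio (> 0; `Inf` = noise-free)
#' @param between_subject_sd log-normal SD of the per-subject dwell factor
#' @param seed master integer seed; all randomness derives from it
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_subjects = 21,
                           conditions = c("wake", "LOC", "ROC"),
                           n_channels = 60,
                           K = 7,
                           rate = 250,
                           duration_s = c(wake = 300, LOC = 300, ROC = 180),
                           dwell_mean_ms = c(wake = 80, LOC = 120, ROC = 80 / 1.3),
                           dwell_shape = 2,
                           carrier_bands = NULL,
                           snr = 4,
                           between_subject_sd = 0.1,
                           seed = 1L) {
  if (is.null(carrier_bands)) {
    carrier_bands <- list(
      wake = list(c(1, 4, 0.6), c(8, 15, 1.0), c(15, 30, 0.8), c(30, 45, 0.5)),
      LOC  = list(c(1, 4, 1.6), c(8, 15, 1.4), c(15, 30, 0.7), c(30, 45, 0.4)),
      ROC  = list(c(1, 4, 0.8), c(8, 15, 0.9), c(15, 30, 0.8), c(30, 45, 0.5)))
    carrier_bands <- carrier_bands[conditions]
    if (any(vapply(carrier_bands, is.null, logical(1))))
      carrier_bands <- stats::setNames(
        rep(list(list(c(1, 4, 1), c(8, 15, 1))), length(conditions)), conditions)
  }
  assert_that(all(unlist(dwell_mean_ms) > 0), "dwell_mean_ms must be > 0")
  assert_that(snr > 0, "snr must be > 0")
  assert_that(K >= 2, "K must be >= 2")
  maxf <- max(vapply(unlist(carrier_bands, recursive = FALSE),
                     function(b) b[2], numeric(1)))
  assert_that(rate > 2 * maxf, "rate must exceed twice the top carrier frequency")
  assert_that(all(conditions %in% names(duration_s)) &&
                all(conditions %in% names(dwell_mean_ms)),
              "duration_s and dwell_mean_ms must name every condition")
  structure(list(n_subjects = n_subjects, conditions = conditions,
                 n_channels = n_channels, K = K, rate = rate,
                 duration_s = duration_s, dwell_mean_ms = dwell_mean_ms,
                 dwell_shape = dwell_shape, carrier_bands = carrier_bands,
                 snr = snr, between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a semi-Markov microstate label sequence
#'
#' Dwell times are gamma(shape = `dwell_shape`, mean = per-class dwell mean),
#' rounded to at least one sample; the next class is drawn uniformly among
#' the other K-1 (no self-transitions — for K = 2 the labels alternate).
#'
#' @param spec a [synthetic_spec()]
#' @param condition condition name (selects the dwell mean)
#' @param seed integer seed
#' @param dwell_mean_ms optional override: scalar or length-K vector of mean
#'   dwell per class (ms)
#' @return integer vector of per-sample class labels covering the condition's
#'   duration
#' @export
sample_state_sequence <- function(spec, condition, seed,
                                  dwell_mean_ms = NULL) {
  n <- as.integer(round(spec$duration_s[[condition]] * spec$rate))
  K <- spec$K
  mu <- dwell_mean_ms %||% spec$dwell_mean_ms[[condition]]
  mu <- rep_len(mu, K)
  with_seed(seed, {
    labels <- integer(n)
    t0 <- 1L
    state <- sample.int(K, 1)
    while (t0 <= n) {
      d_ms <- stats::rgamma(1, shape = spec$dwell_shape,
                            scale = mu[state] / spec$dwell_shape)
      len <- max(1L, as.integer(round(d_ms / 1000 * spec$rate)))
      t1 <- min(n, t0 + len - 1L)
      labels[t0:t1] <- state
      t0 <- t1 + 1L
      state <- if (K == 2) 3L - state else {
        cand <- setdiff(seq_len(K), state)
        cand[sample.int(K - 1L, 1)]
      }
    }
    labels
  })
}

# band-limited noise carrier: white noise band-passed with the package's
# own Butterworth, scaled to unit RMS
band_noise <- function(n, low, high, rate) {
  des <- butter_bandpass_sos(3, low, high, rate)
  x <- stats::rnorm(n + 2 * rate)
  y <- sosfilt(x, des$sos)[(rate + 1):(rate + n)]
  y / stats::sd(y)
}

#' Synthesize a recording from a label sequence and templates
#'
#' `signal(t) = a(t) * template[, label(t)] + noise`, where the amplitude
#' envelope `a(t)` is the rectified (absolute-valued) weighted sum of
#' band-limited noise carriers for the condition, and the noise is spatially
#' white Gaussian with power `mean signal power / snr`. The output is
#' average-referenced. A carrier mix dominated by alpha-range components
#' keeps the GFP peak spacing well below typical dwell times, which the
#' back-fitting stage relies on.
#'
#' @param spec a [synthetic_spec()]
#' @param labels per-sample labels from [sample_state_sequence()]
#' @param templates channels x K template matrix
#' @param seed integer seed
#' @param condition condition name (selects carrier bands)
#' @param subject subject tag
#' @param layout optional [eeg_layout()] (defaults to a generated montage of
#'   matching size)
#' @return an [eeg_recording()]; pair it with ground truth via
#'   [generate_cohort()]
#' @export
synthesize_recording <- function(spec, labels, templates, seed,
                                 condition = spec$conditions[1],
                                 subject = "S01",
                                 layout = NULL) {
  n <- length(labels)
  assert_that(n > 0, "labels must cover the recording")
  bands <- spec$carrier_bands[[condition]]
  maxf <- max(vapply(bands, function(b) b[2], numeric(1)))
  assert_that(spec$rate > 2 * maxf, "carrier band violates Nyquist")
  layout <- layout %||% make_layout(nrow(templates), spec$seed)
  with_seed(seed, {
    a <- rep(0, n)
    for (b in bands)
      a <- a + b[3] * abs(band_noise(n, b[1], b[2], spec$rate))
    X <- templates[, labels, drop = FALSE] * rep(a, each = nrow(templates))
    dimnames(X) <- NULL
    if (is.finite(spec$snr)) {
      # compensate for the power the average reference removes from white
      # noise (factor (C-1)/C), so the emitted recording realizes `snr`
      C <- nrow(templates)
      psig <- mean(X^2)
      sd_n <- sqrt(psig / spec$snr * C / (C - 1))
      X <- X + matrix(stats::rnorm(length(X), sd = sd_n), nrow(X))
    }
    average_reference(
      eeg_recording(X, spec$rate, layout, subject = subject,
                    condition = condition))
  })
}

# realized per-class statistics of a label sequence (all segments included)
realized_metrics <- function(labels, rate, K) {
  r <- rle(labels)
  n <- length(labels)
  out <- data.frame(class = seq_len(K), duration_ms = NA_real_,
                    occurrence_per_s = 0, coverage_fraction = 0)
  for (k in seq_len(K)) {
    sel <- r$values == k
    if (!any(sel)) next
    out$duration_ms[k] <- mean(r$lengths[sel]) / rate * 1000
    out$occurrence_per_s[k] <- sum(sel) / (n / rate)
    out$coverage_fraction[k] <- sum(r$lengths[sel]) / n
  }
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' One recording per subject x condition. Per-subject dwell means are
#' jittered by a log-normal factor (`between_subject_sd`); condition effects
#' enter through the per-condition dwell means and carrier bands of the
#' spec. Every recording is paired with its ground truth: the templates,
#' the true label sequence, and the realized per-class dwell/occurrence/
#' coverage.
#'
#' @param spec a [synthetic_spec()]
#' @return object of class `synthetic_cohort`: `layout`, `templates`,
#'   `spec`, and `recordings` — a list with one element per subject x
#'   condition, each holding `recording` and `truth`
#' @export
generate_cohort <- function(spec) {
  layout <- make_layout(spec$n_channels, derive_seed(spec$seed, 11L))
  templates <- make_templates(spec$K, layout, derive_seed(spec$seed, 13L))
  recs <- list()
  for (s in seq_len(spec$n_subjects)) {
    jit <- if (spec$between_subject_sd > 0)
      with_seed(derive_seed(spec$seed, 17L, s),
                exp(stats::rnorm(1, 0, spec$between_subject_sd)))
    else 1
    for (ci in seq_along(spec$conditions)) {
      cond <- spec$conditions[ci]
      mu <- spec$dwell_mean_ms[[cond]] * jit
      lab_seed <- derive_seed(spec$seed, 1000L, s, ci)
      labels <- sample_state_sequence(spec, cond, lab_seed,
                                      dwell_mean_ms = mu)
      rec <- synthesize_recording(spec, labels, templates,
                                  derive_seed(spec$seed, 2000L, s, ci),
                                  condition = cond,
                                  subject = sprintf("S%02d", s),
                                  layout = layout)
      truth <- list(templates = templates, state_sequence = labels,
                    dwell_mean_ms = rep_len(mu, spec$K),
                    metrics = realized_metrics(labels, spec$rate, spec$K))
      recs[[sprintf("S%02d_%s", s, cond)]] <-
        list(recording = rec, truth = truth)
    }
  }
  structure(list(layout = layout, templates = templates, spec = spec,
                 recordings = recs),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects x %d conditions, K=%d, %d ch @ %g Hz>\n",
              x$spec$n_subjects, length(x$spec$conditions), x$spec$K,
              x$spec$n_channels, x$spec$rate))
  invisible(x)
}
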
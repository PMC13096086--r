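# IIR Butterworth band-pass design, zero-phase filtering, and polyphase
# resampling. No filter-design package ships with the supported stack, so
# these primitives are implemented here: analog Butterworth prototype ->
# band-pass transform -> bilinear transform, realized as second-order
# sections (a 10th-degree transfer function in direct form is numerically
# fragile for a 1 Hz edge at 250 Hz).

# Design an order-n Butterworth band-pass as second-order sections.
# Returns a list(sos = nsec x 6 matrix [b0 b1 b2 1 a1 a2]).
butter_bandpass_sos <- function(order, low, high, rate) {
  assert_that(low > 0 && high > low, "need 0 < low < high")
  assert_that(high < rate / 2, "band edge must be below Nyquist")
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low / rate)   # prewarped analog edges (rad/s)
  w2 <- fs2 * tan(pi * high / rate)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_lp <- complex(real = -sin(theta), imaginary = cos(theta))  # unit-circle LHP
  # low-pass -> band-pass: each prototype pole yields two analog poles
  half <- p_lp * bw / 2
  disc <- sqrt(half^2 - w0^2)
  p_bp <- c(half + disc, half - disc)
  # bilinear transform of poles; zeros: order at z=+1, order at z=-1
  zp <- (fs2 + p_bp) / (fs2 - p_bp)
  # group digital poles into conjugate (or real) pairs
  im <- Im(zp)
  cplx <- zp[im > 1e-9]
  real_p <- Re(zp[abs(im) <= 1e-9])
  pairs <- lapply(cplx, function(p) c(p, Conj(p)))
  if (length(real_p) > 0) {
    real_p <- sort(real_p)
    pairs <- c(pairs, lapply(seq_len(length(real_p) / 2), function(i)
      complex(real = real_p[c(2 * i - 1, 2 * i)])))
  }
  assert_that(length(pairs) == order, "internal: pole pairing failed")
  sos <- t(vapply(pairs, function(pp) {
    a1 <- -Re(pp[1] + pp[2]); a2 <- Re(pp[1] * pp[2])
    c(1, 0, -1, 1, a1, a2)   # numerator (z-1)(z+1) per section
  }, numeric(6)))
  # normalize overall gain to 1 at the (digital image of the) center frequency
  f0 <- atan(w0 / fs2) * rate / pi
  z <- exp(2i * pi * f0 / rate)
  H <- prod(vapply(seq_len(order), function(i) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    abs((b[1] + b[2] / z + b[3] / z^2) / (a[1] + a[2] / z + a[3] / z^2))
  }, numeric(1)))
  sos[, 1:3] <- sos[, 1:3] * (1 / H)^(1 / order)
  list(sos = sos, order = order, low = low, high = high, rate = rate)
}

# single biquad, zero initial state, via stats::filter (C loops)
biquad_filter <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), filter = b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-(1:2)]
  as.numeric(stats::filter(v, filter = -a[2:3], method = "recursive"))
}

sosfilt <- function(x, sos) {
  for (i in seq_len(nrow(sos))) x <- biquad_filter(x, sos[i, 1:3], sos[i, 4:6])
  x
}

# Zero-phase (forward-backward) filtering with odd-reflection padding long
# enough for the slow transients of a 1 Hz edge to die inside the pad.
sosfiltfilt <- function(x, sos, padlen) {
  n <- length(x)
  padlen <- min(n - 1, padlen)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- c(pre, x, post)
  y <- sosfilt(y, sos)
  y <- rev(sosfilt(rev(y), sos))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase; effective magnitude response is the squared single-pass
#' response), realized as second-order sections. The default order 5 with the
#' broadband 1-45 Hz band mirrors the standard preprocessing idiom
#' (MATLAB `filtfilt`).
#'
#' @param recording an [eeg_recording()]
#' @param band a [band_definition()]
#' @param order per-pass Butterworth order (default 5)
#' @return the filtered recording with its `band` tag set
#' @export
bandpass <- function(recording, band, order = 5) {
  assert_that(inherits(band, "band_definition"), "band must be a band_definition")
  assert_that(band$high < recording$rate / 2,
              "band high edge must be below Nyquist")
  des <- butter_bandpass_sos(order, band$low, band$high, recording$rate)
  # pad by ~10 time constants of the slowest pole (low-edge limited)
  padlen <- as.integer(ceiling(10 * recording$rate / band$low))
  out <- t(apply(recording$data, 1, sosfiltfilt, sos = des$sos,
                 padlen = padlen))
  recording$data <- out
  recording$band <- band$name
  recording
}

# ---- resampling ------------------------------------------------------------

kaiser_window <- function(n, beta) {
  i0 <- function(x) besselI(x, 0)
  k <- seq(0, n - 1)
  i0(beta * sqrt(1 - ((2 * k) / (n - 1) - 1)^2)) / i0(beta)
}

msinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Anti-aliased polyphase resampling
#'
#' Resamples each channel by the rational factor `target_rate / rate` using
#' zero-stuffing, a Kaiser-windowed sinc low-pass (10 taps per phase,
#' beta = 5), and decimation — the standard polyphase idiom. Duration is
#' preserved to within one sample.
#'
#' @param recording an [eeg_recording()]
#' @param target_rate desired rate in Hz (must be <= current rate)
#' @return the resampled recording
#' @export
resample <- function(recording, target_rate) {
  assert_that(is.numeric(target_rate) && target_rate > 0,
              "target_rate must be positive")
  assert_that(target_rate <= recording$rate,
              "upsampling is not supported (target_rate > rate)")
  if (target_rate == recording$rate) return(recording)
  frac <- target_rate / recording$rate
  # smallest rational p/q within 1e-9
  q <- which(abs(frac * seq_len(10000) - round(frac * seq_len(10000))) < 1e-9)[1]
  assert_that(!is.na(q), "rate ratio is not a manageable rational number")
  p <- as.integer(round(frac * q))
  g <- gcd_int(p, q); p <- p %/% g; q <- q %/% g
  maxpq <- max(p, q)
  half <- 10L * maxpq
  h <- msinc((seq(-half, half)) / maxpq) * kaiser_window(2L * half + 1L, 5)
  h <- h / sum(h) * p
  n <- ncol(recording$data)
  n_out <- as.integer(ceiling(n * p / q))
  # reflect-pad the input so the filter edge transient falls in the pad
  padin <- as.integer(ceiling(half / p)) + 1L
  out <- t(apply(recording$data, 1, function(x) {
    xp <- c(2 * x[1] - x[seq(padin + 1, 2)], x,
            2 * x[n] - x[seq(n - 1, n - padin)])
    up <- numeric(length(xp) * p)
    up[seq(1, length(up), by = p)] <- xp
    y <- stats::convolve(up, rev(h), type = "open")
    # center of h aligns at offset `half`; skip the input padding (padin*p)
    idx <- half + padin * p + 1 + (seq_len(n_out) - 1) * q
    y[idx]
  }))
  recording$data <- out
  recording$rate <- target_rate
  recording
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
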
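#' Electrode layout on the unit disk
#'
#' A layout holds channel names and 2-D positions on the projected scalp
#' (unit disk, nose towards +y, right ear towards +x). Layouts carry the
#' geometry needed by the smooth-topography generators and the canonical
#' template builder; no 10-20 montage fidelity is claimed.
#'
#' @param labels character vector of unique channel names
#' @param positions numeric matrix (channels x 2) with rows inside the unit disk
#' @return an object of class `eeg_layout`: list with `labels` and `positions`
#' @export
eeg_layout <- function(labels, positions) {
  positions <- as.matrix(positions)
  assert_that(length(labels) >= 2, "a layout needs at least 2 channels")
  assert_that(!anyDuplicated(labels), "channel labels must be unique")
  assert_that(nrow(positions) == length(labels) && ncol(positions) == 2,
              "positions must be a (channels x 2) matrix matching labels")
  assert_that(all(is.finite(positions)), "positions must be finite")
  assert_that(all(sqrt(rowSums(positions^2)) <= 1 + 1e-9),
              "positions must lie within the unit disk")
  structure(list(labels = as.character(labels), positions = positions),
            class = "eeg_layout")
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf("<eeg_layout: %d channels>\n", length(x$labels)))
  invisible(x)
}

n_channels <- function(layout) length(layout$labels)

#' Generate a quasi-uniform electrode layout
#'
#' Places `n_channels` electrodes quasi-uniformly on the unit disk using a
#' sunflower (Fibonacci) spiral with a small seeded jitter, so two calls with
#' the same arguments produce identical layouts.
#'
#' @param n_channels number of electrodes (>= 2)
#' @param seed integer seed controlling the jitter
#' @return an [eeg_layout()]
#' @export
make_layout <- function(n_channels, seed = 0L) {
  assert_that(is.numeric(n_channels) && n_channels >= 2,
              "n_channels must be >= 2")
  n_channels <- as.integer(n_channels)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_channels)
  r <- sqrt((k - 0.5) / n_channels) * 0.95
  th <- k * golden
  pos <- with_seed(derive_seed(seed, 101L), {
    jit <- matrix(stats::rnorm(2 * n_channels, sd = 0.01), ncol = 2)
    cbind(r * cos(th), r * sin(th)) + jit
  })
  # clip the jittered points back into the disk
  rad <- sqrt(rowSums(pos^2))
  over <- rad > 1
  pos[over, ] <- pos[over, ] / rad[over]
  eeg_layout(sprintf("CH%03d", k), pos)
}

# Low-order polynomial spatial basis evaluated at electrode positions;
# columns beyond the constant give smooth, dipolar/gradient-like fields.
smooth_basis <- function(layout) {
  x <- layout$positions[, 1]; y <- layout$positions[, 2]
  cbind(x, y, x * y, x^2 - y^2, x^2 + y^2, x^3, y^3, x^2 * y, x * y^2)
}

normalize_map <- function(v) {
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  assert_that(n > 0, "degenerate (constant) topography")
  v / n
}

#' Generate K smooth, mutually distinct reference topographies
#'
#' Draws random coefficients over a low-order polynomial basis of the
#' electrode positions, producing dipolar/gradient-like maps. Candidates are
#' accepted only if their absolute spatial correlation with every previously
#' accepted map stays below `max_abs_cor`; rejected candidates are
#' residualized against the accepted set, so the procedure terminates for
#' K up to the basis size. Maps are zero-mean, unit L2 norm.
#'
#' @param K number of topographies (2 <= K <= channels)
#' @param layout an [eeg_layout()]
#' @param seed integer seed
#' @param max_abs_cor pairwise absolute-correlation ceiling (default 0.7)
#' @return channels x K matrix, columns unit-norm zero-mean maps
#' @export
make_templates <- function(K, layout, seed = 0L, max_abs_cor = 0.7) {
  assert_that(K >= 1, "K must be >= 1")
  assert_that(K <= n_channels(layout), "K must not exceed the channel count")
  B <- smooth_basis(layout)
  assert_that(K <= ncol(B), sprintf("at most %d templates supported", ncol(B)))
  with_seed(derive_seed(seed, 202L), {
    maps <- matrix(0, nrow(B), 0)
    while (ncol(maps) < K) {
      cand <- normalize_map(drop(B %*% stats::rnorm(ncol(B))))
      if (ncol(maps) > 0) {
        r <- abs(drop(crossprod(maps, cand)))
        if (any(r >= max_abs_cor)) {
          # push the candidate away from the accepted maps
          cand <- cand - maps %*% drop(crossprod(maps, cand))
          ok <- sqrt(sum(cand^2)) > 1e-8
          if (!ok) next
          cand <- normalize_map(drop(cand))
          if (any(abs(drop(crossprod(maps, cand))) >= max_abs_cor)) next
        }
      }
      maps <- cbind(maps, cand)
    }
    colnames(maps) <- paste0("T", seq_len(K))
    maps
  })
}
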
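#' Multichannel EEG recording
#'
#' The basic container moved through the pipeline: a channels x samples
#' potential matrix in microvolts, its sampling rate, the electrode layout,
#' and subject/condition tags. An optional `band` tag records which frequency
#' band the data have been filtered into.
#'
#' @param data channels x samples numeric matrix (microvolts)
#' @param rate sampling rate in Hz
#' @param layout an [eeg_layout()] whose channels match the rows of `data`
#' @param subject subject identifier
#' @param condition one of `"wake"`, `"LOC"`, `"ROC"` (or any tag)
#' @param band optional band name tag
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, rate, layout, subject = NA_character_,
                          condition = NA_character_, band = NULL) {
  data <- as.matrix(data)
  assert_that(is.numeric(rate) && rate > 0, "rate must be positive")
  assert_that(all(is.finite(data)), "data must be finite")
  assert_that(nrow(data) == n_channels(layout),
              "data rows must match the layout channel count")
  structure(list(data = data, rate = rate, layout = layout,
                 subject = subject, condition = condition, band = band),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d ch x %d samples @ %g Hz, subject=%s, condition=%s%s>\n",
              nrow(x$data), ncol(x$data), x$rate, x$subject, x$condition,
              if (is.null(x$band)) "" else paste0(", band=", x$band)))
  invisible(x)
}

#' Frequency band definition
#'
#' @param name band name
#' @param low,high band edges in Hz (0 < low < high)
#' @return object of class `band_definition`
#' @export
band_definition <- function(name, low, high) {
  assert_that(low > 0 && high > low, "need 0 < low < high")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Canonical analysis bands
#'
#' The six bands used throughout: broadband 1-45, delta 1-4, theta 4-8,
#' alpha 8-15, beta 15-30, gamma 30-45 Hz. Alpha/beta edges follow the
#' methods convention (8-15 / 15-30 Hz); edges are configurable by building
#' your own list of [band_definition()]s.
#'
#' @param which character vector of band names to return (default all six)
#' @return named list of [band_definition()]s
#' @export
default_bands <- function(which = c("broadband", "delta", "theta",
                                    "alpha", "beta", "gamma")) {
  all <- list(
    broadband = band_definition("broadband", 1, 45),
    delta     = band_definition("delta", 1, 4),
    theta     = band_definition("theta", 4, 8),
    alpha     = band_definition("alpha", 8, 15),
    beta      = band_definition("beta", 15, 30),
    gamma     = band_definition("gamma", 30, 45))
  assert_that(all(which %in% names(all)), "unknown band name")
  all[which]
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean over channels, so the
#' column means of the result are zero. Idempotent.
#'
#' @param recording an [eeg_recording()]
#' @return the re-referenced recording
#' @export
average_reference <- function(recording) {
  assert_that(nrow(recording$data) >= 2, "need >= 2 channels")
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}
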
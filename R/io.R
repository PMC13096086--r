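# Recording IO: EDF (16-bit European Data Format) and a packaged
# binary-array + JSON-sidecar format, plus tidy CSV/JSON exports.

#' Write / read a recording as raw array + JSON sidecar
#'
#' The packaged format is a little-endian float64 binary (`.bin`,
#' channel-major) next to a JSON sidecar (`.json`) holding rate, labels,
#' positions, subject, condition and band. Round-trips are bit-identical.
#'
#' @param recording an [eeg_recording()]
#' @param path output path without extension (or with `.bin`)
#' @return (write) the path, invisibly; (read) an [eeg_recording()]
#' @export
write_recording_array <- function(recording, path) {
  path <- sub("\\.bin$", "", path)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 8, endian = "little")
  side <- list(rate = recording$rate,
               n_channels = nrow(recording$data),
               n_samples = ncol(recording$data),
               labels = recording$layout$labels,
               positions = unname(apply(recording$layout$positions, 1,
                                        as.numeric, simplify = FALSE)),
               subject = recording$subject,
               condition = recording$condition,
               band = recording$band)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, ".bin"))
}

#' @rdname write_recording_array
#' @export
read_recording_array <- function(path) {
  path <- sub("\\.bin$", "", path)
  sidecar <- paste0(path, ".json")
  assert_that(file.exists(sidecar),
              paste0("missing sidecar: ", sidecar))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- side$n_channels * side$n_samples
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  assert_that(length(x) == n, "truncated .bin payload")
  pos <- if (is.matrix(side$positions)) side$positions
         else do.call(rbind, side$positions)
  lay <- eeg_layout(side$labels, pos)
  eeg_recording(matrix(x, side$n_channels), side$rate, lay,
                subject = side$subject, condition = side$condition,
                band = side$band)
}

# ---- EDF -------------------------------------------------------------------

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write / read a recording as EDF
#'
#' Minimal European Data Format support: 16-bit samples, one data record per
#' second (integer rates only), physical range set symmetrically to the data
#' maximum, so the round-trip error is bounded by one quantization step
#' `(2 * max|x|) / 65535`. Subject and condition ride in the patient /
#' recording-id header fields.
#'
#' @param recording an [eeg_recording()] with integer sampling rate
#' @param path output `.edf` path
#' @return (write) `path` invisibly; (read) an [eeg_recording()] (layout
#'   positions are not stored in EDF; a generated layout of matching size is
#'   attached)
#' @export
write_recording_edf <- function(recording, path) {
  fs <- recording$rate
  assert_that(fs == round(fs), "EDF writer requires an integer rate")
  C <- nrow(recording$data); n <- ncol(recording$data)
  n_rec <- floor(n / fs)
  assert_that(n_rec >= 1, "recording shorter than one EDF data record (1 s)")
  X <- recording$data[, seq_len(n_rec * fs), drop = FALSE]
  pmax <- max(abs(X), 1e-6)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(paste0("X X X ", recording$subject), 80)
  wr(paste0("Startdate X X X ", recording$condition), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + C)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(C), 4)
  for (lab in recording$layout$labels) wr(lab, 16)
  for (i in seq_len(C)) wr("EEG", 80)
  for (i in seq_len(C)) wr("uV", 8)
  for (i in seq_len(C)) wr(sprintf("%.5g", -pmax), 8)
  for (i in seq_len(C)) wr(sprintf("%.5g", pmax), 8)
  for (i in seq_len(C)) wr(as.character(dmin), 8)
  for (i in seq_len(C)) wr(as.character(dmax), 8)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr(as.character(fs), 8)
  for (i in seq_len(C)) wr("", 32)
  scale <- (dmax - dmin) / (2 * pmax)
  for (r in seq_len(n_rec)) {
    seg <- X[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((seg + pmax) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    assert_that(nchar(s, type = "bytes") == w,
                paste0("corrupt EDF header in ", path))
    trimws(s)
  }
  rd(8)
  pat <- rd(80); recf <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rd(8)
  C <- as.integer(rd(4))
  assert_that(is.finite(C) && C >= 1, paste0("corrupt EDF header in ", path))
  labels <- vapply(seq_len(C), function(i) rd(16), character(1))
  for (i in seq_len(C)) rd(80)
  for (i in seq_len(C)) rd(8)
  pmin_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  pmax_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  dmin_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  dmax_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  for (i in seq_len(C)) rd(80)
  fs <- as.integer(vapply(seq_len(C), function(i) rd(8), character(1)))
  for (i in seq_len(C)) rd(32)
  n <- n_rec * fs[1]
  raw <- readBin(con, "integer", n = n_rec * sum(fs), size = 2,
                 endian = "little")
  assert_that(length(raw) == n_rec * sum(fs), "truncated EDF payload")
  X <- matrix(0, C, n)
  off <- 0
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(C)) {
      idx <- off + seq_len(fs[ch])
      g <- (pmax_v[ch] - pmin_v[ch]) / (dmax_v[ch] - dmin_v[ch])
      X[ch, ((r - 1) * fs[ch] + 1):(r * fs[ch])] <-
        (raw[idx] - dmin_v[ch]) * g + pmin_v[ch]
      off <- off + fs[ch]
    }
  }
  subject <- sub("^X X X ", "", pat)
  condition <- sub("^Startdate X X X ", "", recf)
  eeg_recording(X, fs[1], make_layout(C, 0L), subject = subject,
                condition = condition)
}

#' Export a label sequence as run-length CSV
#'
#' @param seq a [backfit()] result
#' @param path CSV path
#' @return the data.frame written, invisibly
#' @export
write_label_sequence <- function(seq, path) {
  segs <- seq$segments
  out <- data.frame(class = seq$class_labels[segs$class],
                    start_s = (segs$start - 1) / seq$rate,
                    end_s = segs$end / seq$rate,
                    truncated = segs$truncated)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Serialize a microstate model to JSON
#'
#' @param model a `microstate_model`
#' @param path JSON path
#' @return `path` invisibly; `read_model_json` returns the model
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(K = model$K,
                            maps = unname(apply(model$maps, 2, as.numeric,
                                                simplify = FALSE)),
                            labels = model$labels,
                            gev_total = model$gev_total,
                            ev_per_class = model$ev_per_class,
                            cv_value = model$cv_value,
                            level = model$level, band = model$band),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- if (is.matrix(j$maps)) t(j$maps) else do.call(cbind, j$maps)
  structure(list(K = j$K, maps = maps,
                 assignment = NULL,
                 gev_total = j$gev_total %||% NA_real_,
                 ev_per_class = j$ev_per_class %||% rep(NA_real_, j$K),
                 cv_value = j$cv_value %||% NA_real_,
                 labels = j$labels, level = j$level, band = j$band),
            class = "microstate_model")
}
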
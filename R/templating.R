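# Multi-level map averaging, canonical template sorting (A-G), back-fitting
# with midpoint interpolation, and temporal microstate metrics.

#' Synthetic canonical microstate templates A-G
#'
#' Builds seven labeled reference topographies on a given layout from the
#' textual descriptions of the classic normative maps: A left-posterior to
#' right-frontal gradient, B right-posterior to left-frontal gradient,
#' C anterior-posterior gradient, D fronto-central maximum, E left-right
#' gradient, F occipito-central maximum, G central-posterior maximum.
#' These are geometric stand-ins (the normative maps themselves are not
#' distributed), adequate for deterministic sorting and labeling; they are
#' not the published template data.
#'
#' @param layout an [eeg_layout()]
#' @return channels x 7 matrix with columns "A".."G", unit-norm zero-mean
#' @export
canonical_templates <- function(layout) {
  x <- layout$positions[, 1]; y <- layout$positions[, 2]
  bump <- function(cx, cy, s) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  maps <- cbind(
    A = (x + y) / sqrt(2),
    B = (y - x) / sqrt(2),
    C = y,
    D = bump(0, 0.45, 0.35),
    E = x,
    F = bump(0, -0.65, 0.28),
    G = bump(0, -0.15, 0.55))
  apply(maps, 2, normalize_map)
}

#' Polarity-aligned average of microstate models
#'
#' Averages matched classes across models: within each class every
#' contributing map is flipped, if needed, to correlate positively with a
#' running reference (the first model's map, then the running average), the
#' flipped maps are averaged and the result re-normalized. Models must share
#' K and channel count and already be sorted into a common class order.
#'
#' @param models list of `microstate_model`s
#' @param level level tag of the output (`"condition"` or `"grand"`)
#' @return a `microstate_model` holding the mean maps (GEV fields NA)
#' @export
mean_maps <- function(models, level = "condition") {
  assert_that(length(models) >= 1, "need at least one model")
  K <- models[[1]]$K
  C <- nrow(models[[1]]$maps)
  ok <- vapply(models, function(m) m$K == K && nrow(m$maps) == C, logical(1))
  assert_that(all(ok), "models must share K and channel count")
  out <- matrix(0, C, K)
  for (k in seq_len(K)) {
    ref <- models[[1]]$maps[, k]
    acc <- rep(0, C)
    for (m in models) {
      v <- m$maps[, k]
      if (sum(v * ref) < 0) v <- -v
      acc <- acc + v
      ref <- acc / max(sqrt(sum(acc^2)), 1e-12)
    }
    out[, k] <- normalize_map(acc)
  }
  structure(list(K = K, maps = out, assignment = NULL,
                 gev_total = NA_real_, ev_per_class = rep(NA_real_, K),
                 cv_value = NA_real_,
                 labels = models[[1]]$labels, level = level,
                 band = models[[1]]$band),
            class = "microstate_model")
}

#' Sort model classes against reference templates
#'
#' Finds the one-to-one class-to-template assignment maximizing the summed
#' absolute spatial correlation (Hungarian algorithm via
#' [clue::solve_LSAP()]), reorders and relabels the model's maps to the
#' template labels, and flips each map so its correlation with the assigned
#' template is positive.
#'
#' @param model a `microstate_model` with `K <=` number of templates
#' @param templates channels x m matrix of labeled reference maps (e.g.
#'   [canonical_templates()]) or another model's `maps`
#' @return the model, reordered/relabeled, with an added `sort_correlation`
#'   vector (correlation with the assigned template per class)
#' @export
sort_by_template <- function(model, templates) {
  templates <- as.matrix(templates)
  assert_that(nrow(templates) == nrow(model$maps),
              "templates and model must share the channel space")
  K <- model$K; m <- ncol(templates)
  assert_that(K <= m, "model has more classes than templates")
  R <- crossprod(normalize_columns(model$maps), normalize_columns(templates))
  sol <- clue::solve_LSAP(abs(R[, , drop = FALSE]) + 1e-12, maximum = TRUE)
  tpl_for_class <- as.integer(sol)   # class k -> template index
  ord <- order(tpl_for_class)
  maps <- model$maps[, ord, drop = FALSE]
  tsel <- tpl_for_class[ord]
  rr <- numeric(K)
  for (j in seq_len(K)) {
    r <- spatial_cor(maps[, j], templates[, tsel[j]])
    if (r < 0) { maps[, j] <- -maps[, j]; r <- -r }
    rr[j] <- r
  }
  labels <- colnames(templates)[tsel] %||% paste0("M", tsel)
  model$maps <- maps
  model$labels <- labels
  model$sort_correlation <- stats::setNames(rr, labels)
  if (!is.null(model$ev_per_class)) model$ev_per_class <- model$ev_per_class[ord]
  model$assignment <- NULL
  model
}

#' Back-fit microstate maps to a continuous recording
#'
#' Labels every GFP peak with the class of highest absolute spatial
#' correlation, then interpolates between adjacent peaks: each label runs
#' from halfway after the previous peak to halfway before the next (the left
#' segment keeps the extra sample on even gaps). Samples before the first and
#' after the last peak stay unassigned, and the first and last complete
#' segments are flagged truncated (excluded from the temporal metrics).
#'
#' @param recording an [eeg_recording()] (average-referenced; band should
#'   match the model's band)
#' @param model a `microstate_model` (typically sorted grand-mean maps)
#' @return object of class `label_sequence`: integer `labels` (NA where
#'   unassigned), class `labels` names, `rate`, `segments` data.frame
#'   (class, start, end, truncated), `peak_indices`, `peak_labels`
#' @export
backfit <- function(recording, model) {
  gfp <- compute_gfp(recording)
  n <- ncol(recording$data)
  pk <- gfp$peak_indices
  if (length(pk) == 0) {
    warning("no GFP peaks: empty label sequence")
    return(structure(list(labels = rep(NA_integer_, n),
                          class_labels = model$labels, rate = recording$rate,
                          segments = data.frame(class = integer(0),
                                                start = integer(0),
                                                end = integer(0),
                                                truncated = logical(0)),
                          peak_indices = integer(0),
                          peak_labels = integer(0),
                          gfp = gfp$values, band = recording$band),
                     class = "label_sequence"))
  }
  V <- normalize_columns(recording$data[, pk, drop = FALSE])
  R2 <- crossprod(model$maps, V)^2
  pk_lab <- max.col(t(R2), ties.method = "first")
  labels <- rep(NA_integer_, n)
  if (length(pk) == 1) {
    labels[pk] <- pk_lab
  } else {
    bounds <- floor((pk[-length(pk)] + pk[-1]) / 2)   # left-inclusive midpoint
    starts <- c(pk[1], bounds + 1L)
    ends <- c(bounds, pk[length(pk)])
    for (i in seq_along(pk)) labels[starts[i]:ends[i]] <- pk_lab[i]
  }
  segments <- label_runs(labels)
  if (nrow(segments) > 0) {
    segments$truncated <- FALSE
    segments$truncated[c(1, nrow(segments))] <- TRUE
  }
  structure(list(labels = labels, class_labels = model$labels,
                 rate = recording$rate, segments = segments,
                 peak_indices = pk, peak_labels = pk_lab,
                 gfp = gfp$values, band = recording$band),
            class = "label_sequence")
}

# run-length segments of the labeled (non-NA) span
label_runs <- function(labels) {
  idx <- which(!is.na(labels))
  if (length(idx) == 0)
    return(data.frame(class = integer(0), start = integer(0),
                      end = integer(0), truncated = logical(0)))
  span <- labels[idx[1]:idx[length(idx)]]
  r <- rle(span)
  ends <- cumsum(r$lengths) + idx[1] - 1L
  starts <- ends - r$lengths + 1L
  data.frame(class = r$values, start = starts, end = ends,
             truncated = FALSE)
}

#' Temporal microstate metrics from a label sequence
#'
#' Per class: mean duration (ms) of uninterrupted segments, occurrence
#' (appearances per second) and coverage (fraction of analyzed time).
#' Truncated edge segments are excluded from all three quantities: they are
#' dropped from the duration mean and occurrence count, and their samples
#' are removed from both the coverage numerator and denominator, so coverage
#' still sums to one. A class that never occurs reports duration NA,
#' occurrence 0, coverage 0.
#'
#' @param seq a [backfit()] result (or generator ground-truth sequence)
#' @param include_truncated if TRUE, keep edge segments in the accounting
#' @return data.frame: class (label), duration_ms, occurrence_per_s,
#'   coverage_fraction
#' @export
compute_metrics <- function(seq, include_truncated = FALSE) {
  segs <- seq$segments
  assert_that(nrow(segs) > 0, "empty label sequence")
  if (!include_truncated) segs <- segs[!segs$truncated, , drop = FALSE]
  K <- length(seq$class_labels)
  len <- segs$end - segs$start + 1L
  kept <- sum(len)
  span_s <- kept / seq$rate
  out <- data.frame(class = seq$class_labels,
                    duration_ms = NA_real_,
                    occurrence_per_s = 0,
                    coverage_fraction = 0)
  for (k in seq_len(K)) {
    sel <- segs$class == k
    if (!any(sel)) next
    out$duration_ms[k] <- mean(len[sel]) / seq$rate * 1000
    out$occurrence_per_s[k] <- sum(sel) / span_s
    out$coverage_fraction[k] <- sum(len[sel]) / kept
  }
  out
}

#' Per-class individual explained variance
#'
#' Partitions the model's GEV by back-fitted class: for class c,
#' `IEV_c = sum over peaks labeled c of GFP^2 r^2 / sum over all peaks of
#' GFP^2`. The classes partition the peak set, so `sum(IEV) = GEV` exactly.
#'
#' @param recording the back-fitted [eeg_recording()]
#' @param model the `microstate_model` used for back-fitting
#' @param seq the matching [backfit()] result
#' @return named numeric vector of per-class IEV fractions
#' @export
compute_iev <- function(recording, model, seq) {
  pk <- seq$peak_indices
  assert_that(length(pk) > 0, "no peaks: IEV undefined")
  g2 <- seq$gfp[pk]^2
  assert_that(sum(g2) > 0, "all-zero GFP: IEV undefined")
  V <- normalize_columns(recording$data[, pk, drop = FALSE])
  R2 <- crossprod(model$maps, V)^2
  r2 <- R2[cbind(seq$peak_labels, seq_along(pk))]
  num <- g2 * r2
  iev <- vapply(seq_len(model$K), function(k) sum(num[seq$peak_labels == k]),
                numeric(1))
  stats::setNames(iev / sum(g2), seq$class_labels)
}
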
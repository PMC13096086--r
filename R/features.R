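# Feature assembly and standardization for state classification.

#' Build the classification feature table
#'
#' One row per subject x condition; columns named `band.class.param` with
#' param in duration, occurrence, coverage, ev (the per-class explained
#' variance). A single band yields `K*4` columns (28 for K = 7); the five
#' sub-bands 140; all six bands 168. A class absent from a recording
#' contributes 0 for occurrence/coverage/ev, and its undefined duration is
#' imputed 0 (rows flagged in the `imputed` attribute).
#'
#' @param metrics tidy data.frame with columns subject, condition, band,
#'   class, duration_ms, occurrence_per_s, coverage_fraction, iev
#' @param bands band names to include, in order
#' @return data.frame with `subject`, `condition` and one numeric column per
#'   feature; attribute `imputed` lists imputed duration cells
#' @export
build_features <- function(metrics, bands) {
  need <- c("subject", "condition", "band", "class", "duration_ms",
            "occurrence_per_s", "coverage_fraction", "iev")
  assert_that(all(need %in% names(metrics)),
              "metrics is missing required columns")
  metrics <- metrics[metrics$band %in% bands, , drop = FALSE]
  assert_that(nrow(metrics) > 0, "no rows for the requested bands")
  classes <- sort(unique(as.character(metrics$class)))
  params <- c(duration = "duration_ms", occurrence = "occurrence_per_s",
              coverage = "coverage_fraction", ev = "iev")
  samples <- unique(metrics[, c("subject", "condition")])
  samples <- samples[order(samples$subject, samples$condition), ]
  feat_names <- as.vector(t(outer(bands, as.vector(t(outer(classes, names(params),
                  paste, sep = "."))), paste, sep = ".")))
  X <- matrix(NA_real_, nrow(samples), length(feat_names),
              dimnames = list(NULL, feat_names))
  key <- paste(metrics$subject, metrics$condition, metrics$band, metrics$class)
  imputed <- character(0)
  for (i in seq_len(nrow(samples))) {
    for (b in bands) for (cl in classes) {
      row <- match(paste(samples$subject[i], samples$condition[i], b, cl), key)
      for (pn in names(params)) {
        col <- paste(b, cl, pn, sep = ".")
        v <- if (is.na(row)) NA_real_ else metrics[[params[[pn]]]][row]
        if (is.na(v)) {
          v <- 0
          imputed <- c(imputed, paste0(samples$subject[i], "/",
                                       samples$condition[i], "/", col))
        }
        X[i, col] <- v
      }
    }
  }
  out <- cbind(samples, as.data.frame(X), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "imputed") <- imputed
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), c("subject", "condition")),
                     drop = FALSE])
}

#' Fit / apply column standardization
#'
#' `standardize_fit` learns per-column mean and SD on training rows only;
#' `standardize_apply` transforms any rows with those parameters (so test
#' data never leaks into the statistics). Zero-SD columns are centered with
#' scale 1 and flagged.
#'
#' @param X numeric matrix (training rows)
#' @return `standardize_fit`: list with `mean`, `sd`, `constant` (logical);
#'   `standardize_apply`: the transformed matrix
#' @export
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  constant <- sd == 0 | !is.finite(sd)
  sd[constant] <- 1
  list(mean = mu, sd = sd, constant = constant)
}

#' @rdname standardize_fit
#' @param fit a `standardize_fit` result
#' @export
standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2, fit$mean), 2, fit$sd, "/")
}
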
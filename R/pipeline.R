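# End-to-end orchestration: config validation, staged execution in
# dependency order, and a run manifest with per-artifact checksums.

pipeline_defaults <- function() {
  list(
    simulate = list(n_subjects = 4, conditions = c("wake", "LOC", "ROC"),
                    n_channels = 20, K = 4, rate = 250,
                    duration_s = c(wake = 60, LOC = 60, ROC = 60),
                    snr = 4, between_subject_sd = 0.1),
    bands = list(broadband = c(1, 45)),
    microstate = list(k_range = 2:8, fixed_k = NULL, restarts = 20,
                      tol = 1e-7, max_iter = 300),
    spectral = list(window_s = 2, step_s = 1.5, time_bandwidth = 3,
                    n_tapers = 5),
    backfit = list(include_truncated = FALSE),
    stats = list(alpha = 0.05, lilliefors_nrep = 2000),
    classification = list(model = "linear_svm", cv = "loocv", top_n = 10,
                          paper_mode = FALSE),
    seed = 1L,
    out_dir = NULL)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON config (or accepts a list), fills defaults, and
#' rejects unknown top-level keys with the offending field path.
#'
#' @param config path to a YAML/JSON file or a named list
#' @return validated config list
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  assert_that(length(unknown) == 0,
              paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  for (nm in names(config)) {
    if (is.list(defs[[nm]]) && !is.null(names(defs[[nm]]))) {
      bad <- setdiff(names(config[[nm]]), names(defs[[nm]]))
      if (nm != "bands")
        assert_that(length(bad) == 0,
                    paste0("unknown config field(s): ",
                           paste(paste0(nm, ".", bad), collapse = ", ")))
      defs[[nm]][names(config[[nm]])] <- config[[nm]]
    } else defs[[nm]] <- config[[nm]]
  }
  defs
}

stage_log <- function(stage, seed, detail, t0) {
  message(sprintf("[freqstate] stage=%s seed=%s elapsed=%.1fs %s",
                  stage, seed, as.numeric(Sys.time()) - t0, detail))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: simulate -> prep (per band) ->
#' spectra -> segment (individual-level clustering per subject x condition x
#' band) -> mean maps (condition, grand) -> sort -> backfit -> metrics ->
#' stats -> classify. Artifacts are written under `out_dir` and listed with
#' MD5 checksums in the returned manifest (also written as
#' `manifest.json`).
#'
#' @param config a config path or list (see [load_config()])
#' @param out_dir output directory (overrides the config field)
#' @return the manifest, invisibly: per-stage status and artifact checksums
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop_invalid("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  manifest <- list(package_version = as.character(utils::packageVersion("freqstate")),
                   seed = cfg$seed, stages = list(), artifacts = list())
  art <- function(path) {
    manifest$artifacts[[basename(path)]] <<- unname(tools::md5sum(path))
    path
  }
  done <- function(stage, detail = "") {
    manifest$stages[[stage]] <<- "complete"
    stage_log(stage, cfg$seed, detail, t0)
  }

  # simulate
  sim <- cfg$simulate
  spec <- synthetic_spec(n_subjects = sim$n_subjects,
                         conditions = sim$conditions,
                         n_channels = sim$n_channels, K = sim$K,
                         rate = sim$rate,
                         duration_s = unlist(sim$duration_s),
                         snr = sim$snr,
                         between_subject_sd = sim$between_subject_sd,
                         seed = cfg$seed)
  cohort <- generate_cohort(spec)
  truth_metrics <- do.call(rbind, lapply(names(cohort$recordings), function(nm) {
    tr <- cohort$recordings[[nm]]$truth$metrics
    tr$id <- nm
    tr
  }))
  utils::write.csv(truth_metrics, art(file.path(out_dir, "truth_metrics.csv")),
                   row.names = FALSE)
  done("simulate", sprintf("%d recordings", length(cohort$recordings)))

  bands <- lapply(names(cfg$bands), function(nm)
    band_definition(nm, cfg$bands[[nm]][1], cfg$bands[[nm]][2]))
  names(bands) <- names(cfg$bands)

  # prep + spectra + segment, per recording
  sp <- cfg$spectral
  powers <- list(); metrics_rows <- list(); indiv <- list()
  for (nm in names(cohort$recordings)) {
    rec <- cohort$recordings[[nm]]$recording
    rec <- average_reference(rec)
    psd <- multitaper_psd(rec, sp$window_s, sp$step_s, sp$time_bandwidth,
                          sp$n_tapers)
    bp <- band_power(psd, bands)
    bp$subject <- rec$subject; bp$condition <- rec$condition
    powers[[nm]] <- bp
    for (b in names(bands)) {
      fb <- bandpass(rec, bands[[b]])
      gfp <- compute_gfp(fb)
      pk <- gfp$peak_indices
      km <- cfg$microstate
      K <- km$fixed_k %||% cfg$simulate$K
      indiv[[paste(nm, b, sep = "|")]] <- list(
        model = modified_kmeans(fb$data[, pk, drop = FALSE], K,
                                n_restarts = km$restarts, tol = km$tol,
                                max_iter = km$max_iter,
                                seed = derive_seed(cfg$seed, 31L, match(nm, names(cohort$recordings)), match(b, names(bands))),
                                gfp = gfp$values[pk]),
        recording = fb, band = b, subject = rec$subject,
        condition = rec$condition)
    }
  }
  power_table <- do.call(rbind, powers)
  utils::write.csv(power_table, art(file.path(out_dir, "band_power.csv")),
                   row.names = FALSE)
  done("prep", sprintf("%d bands", length(bands)))
  done("spectra", sprintf("%d rows", nrow(power_table)))
  done("segment", sprintf("%d individual models", length(indiv)))

  # multi-level averaging and sorting per band
  templates <- canonical_templates(cohort$layout)
  grand <- list(); sorted_indiv <- list()
  for (b in names(bands)) {
    sel <- Filter(function(e) e$band == b, indiv)
    conds <- unique(vapply(sel, `[[`, character(1), "condition"))
    cond_models <- lapply(conds, function(cn) {
      ms <- lapply(Filter(function(e) e$condition == cn, sel), `[[`, "model")
      ms <- lapply(ms, sort_by_template, templates = templates)
      mean_maps(ms, level = "condition")
    })
    g <- sort_by_template(mean_maps(cond_models, level = "grand"), templates)
    g$band <- b
    grand[[b]] <- g
    write_model_json(g, art(file.path(out_dir, sprintf("grand_%s.json", b))))
    for (key in names(indiv)) {
      if (indiv[[key]]$band == b)
        sorted_indiv[[key]] <- sort_by_template(indiv[[key]]$model, g$maps)
    }
  }
  done("sort", sprintf("%d grand models of K=%d", length(grand), grand[[1]]$K))

  # backfit + metrics
  for (key in names(indiv)) {
    e <- indiv[[key]]
    g <- grand[[e$band]]
    seq <- backfit(e$recording, g)
    mt <- compute_metrics(seq, include_truncated = cfg$backfit$include_truncated)
    iev <- compute_iev(e$recording, g, seq)
    metrics_rows[[key]] <- data.frame(subject = e$subject,
                                      condition = e$condition, band = e$band,
                                      class = mt$class,
                                      duration_ms = mt$duration_ms,
                                      occurrence_per_s = mt$occurrence_per_s,
                                      coverage_fraction = mt$coverage_fraction,
                                      iev = unname(iev))
  }
  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, art(file.path(out_dir, "metrics.csv")),
                   row.names = FALSE)
  done("backfit", "")
  done("metrics", sprintf("%d rows", nrow(metrics)))

  # group statistics on every band x class x parameter
  stats_rows <- list()
  null_cache <- list()
  for (b in names(bands)) for (param in c("duration_ms", "occurrence_per_s",
                                          "coverage_fraction", "iev")) {
    sub <- metrics[metrics$band == b, ]
    for (cl in unique(sub$class)) {
      d <- sub[sub$class == cl, ]
      tab <- stats::xtabs(stats::as.formula(paste(param, "~ subject + condition")),
                          data = d)
      if (any(is.na(d[[param]])) || nrow(tab) < 3) next
      m <- as.matrix(unclass(tab))
      a <- rm_anova(m)
      pw <- pairwise_bonferroni(m)
      lil <- NA_real_
      if (nrow(m) >= 4) {   # Lilliefors is undefined below n = 4
        key_n <- as.character(nrow(m))
        if (is.null(null_cache[[key_n]]))
          null_cache[[key_n]] <- lilliefors_null(nrow(m),
                                                 cfg$stats$lilliefors_nrep,
                                                 cfg$seed)
        lil <- min(vapply(seq_len(ncol(m)), function(j)
          lilliefors(m[, j], null_stats = null_cache[[key_n]])$p_value,
          numeric(1)))
      }
      stats_rows[[paste(b, param, cl)]] <-
        data.frame(band = b, parameter = param, class = cl,
                   F = a$F, df1 = a$df[1], df2 = a$df[2], p = a$p,
                   lilliefors_min_p = lil,
                   pair = pw$pair, p_corrected = pw$p_corrected)
    }
  }
  stats_table <- do.call(rbind, stats_rows)
  rownames(stats_table) <- NULL
  utils::write.csv(stats_table, art(file.path(out_dir, "stats.csv")),
                   row.names = FALSE)
  done("stats", sprintf("%d comparisons", nrow(stats_table)))

  # classification
  cc <- cfg$classification
  feats <- build_features(metrics, names(bands))
  rep <- evaluate(feats, model = cc$model, cv = cc$cv,
                  nested_selection = !isTRUE(cc$paper_mode),
                  top_n = cc$top_n, seed = cfg$seed)
  jsonlite::write_json(list(model = rep$model, cv = rep$cv_scheme,
                            accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
                            f1 = as.list(rep$f1), auc = as.list(rep$auc),
                            confusion = rep$confusion),
                       art(file.path(out_dir, "classification.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep$predictions,
                   art(file.path(out_dir, "predictions.csv")),
                   row.names = FALSE)
  done("classify", sprintf("accuracy=%.3f", rep$accuracy))

  manifest$elapsed_s <- as.numeric(Sys.time()) - t0
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
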
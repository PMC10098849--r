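# End-to-end pipeline: separate -> detect -> segment -> features ->
# (optionally) classify, with a run log echoing the effective parameters
# and per-stage timing/warnings.

#' Run the full processing pipeline on one record
#'
#' Stage order is fixed: wavelet separation, J-peak detection, breath-frame
#' segmentation, feature extraction, and classification (skipped when no
#' model is supplied). Identical configuration and input give identical
#' outputs.
#'
#' @param record A [raw_record].
#' @param config A `pipeline_config` (defaults used when omitted).
#' @param model Optional `logit_model`; when present a `calls` table with
#'   apnea probabilities and labels is produced.
#' @param stop_after Optional stage name (`"separate"`, `"detect"`,
#'   `"features"`) for a partial run.
#' @return List of class `pipeline_result`: `separated`, `jpeaks`,
#'   `frames`, `features`, `calls` (or `NULL`), `log`.
#' @export
run_pipeline <- function(record, config = pipeline_config(), model = NULL,
                         stop_after = NULL) {
  rec <- as_raw_record(record)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              fs = rec$fs, n_samples = length(rec$samples),
              config = unclass(config), stages = character(0),
              warnings = character(0))
  note <- function(stage) log$stages <<- c(log$stages, stage)
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        log$warnings <<- c(log$warnings,
                           paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  note("separate")
  sep <- run_stage("separate", separate(
    rec, wavelet = config$wavelet$name, levels = config$wavelet$levels,
    include_d5_resp = isTRUE(config$wavelet$include_d5_resp),
    threshold_levels = config$wavelet$threshold_levels,
    detrend = config$wavelet$detrend))
  if (identical(stop_after, "separate")) {
    return(structure(list(separated = sep, jpeaks = NULL, frames = NULL,
                          features = NULL, calls = NULL, log = log),
                     class = "pipeline_result"))
  }

  note("detect")
  params <- detector_params(
    ush_base = config$detector$ush, bias = config$detector$bias,
    dsh = config$detector$dsh, refractory_ms = config$detector$refractory_ms,
    low_factor = config$detector$low_factor,
    high_factor = config$detector$high_factor,
    threshold_relax = config$detector$threshold_relax)
  jp <- run_stage("detect", detect_jpeaks(sep$bcg, sep$fs, params))
  if (identical(stop_after, "detect")) {
    return(structure(list(separated = sep, jpeaks = jp, frames = NULL,
                          features = NULL, calls = NULL, log = log),
                     class = "pipeline_result"))
  }

  note("segment")
  frames <- run_stage("segment", segment_breath_frames(
    sep$respiration, sep$fs,
    prominence_frac = config$feature$prominence_frac,
    min_period_s = config$feature$min_period_s,
    max_period_s = config$feature$max_period_s))

  note("features")
  tmpl <- standard_template(n = config$feature$template_n,
                            inhale_frac = config$feature$inhale_frac)
  feats <- run_stage("features", feature_table(
    sep, jp, frames = frames, template = tmpl,
    cv_reciprocal = isTRUE(config$feature$cv_reciprocal)))
  if (identical(stop_after, "features") || is.null(model)) {
    return(structure(list(separated = sep, jpeaks = jp, frames = frames,
                          features = feats, calls = NULL, log = log),
                     class = "pipeline_result"))
  }

  note("classify")
  calls <- run_stage("classify", {
    Xp <- prepare_design(feats, model$feature_names)
    prob <- predict_proba(model, Xp)
    data.frame(frame_start = feats$frame_start, frame_end = feats$frame_end,
               prob_apnea = prob,
               label = ifelse(prob >= config$classifier$threshold,
                              "apnea", "normal"))
  })
  structure(list(separated = sep, jpeaks = jp, frames = frames,
                 features = feats, calls = calls, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:", paste(x$log$stages, collapse = " -> "), "\n")
  if (!is.null(x$features)) {
    cat("  ", nrow(x$features), "breath frames;",
        length(x$jpeaks$peaks), "J-peaks\n")
  }
  if (!is.null(x$calls)) {
    cat("  ", sum(x$calls$label == "apnea"), "frames called apnea\n")
  }
  invisible(x)
}

#' Label segmented frames against ground-truth apnea events
#'
#' A frame is labelled apnea (1) when more than `min_overlap` of its length
#' overlaps an annotated apnea event.
#'
#' @param features Feature table (or any data frame with 0-based
#'   `frame_start`, `frame_end`).
#' @param truth A `ground_truth` from [synthesize()], or a data frame of
#'   events with `start_sample`, `end_sample`.
#' @param min_overlap Minimum overlapping fraction of the frame
#'   (default 0.5).
#' @return Integer vector of labels in `{0, 1}`, one per frame.
#' @export
label_frames <- function(features, truth, min_overlap = 0.5) {
  ev <- if (inherits(truth, "ground_truth")) truth$apnea_events else truth
  vapply(seq_len(nrow(features)), function(i) {
    fs0 <- features$frame_start[i]
    fe0 <- features$frame_end[i]
    ov <- 0
    if (!is.null(ev) && nrow(ev)) {
      ov <- max(pmin(fe0, ev$end_sample) - pmax(fs0, ev$start_sample), 0)
    }
    as.integer(ov > min_overlap * (fe0 - fs0))
  }, integer(1))
}

#' Build a model design matrix from a feature table
#'
#' Selects the model's feature columns from a [feature_table()] data frame
#' and imputes undefined features (frames with fewer than two beats) with
#' the supplied per-feature medians (training medians at prediction time).
#'
#' @param features Feature-table data frame.
#' @param feature_names Columns to keep, in model order.
#' @param impute Named numeric vector of imputation values; defaults to
#'   the medians of the defined rows of `features` itself.
#' @return Numeric matrix with one row per frame.
#' @export
prepare_design <- function(features, feature_names, impute = NULL) {
  X <- as.matrix(features[, feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (is.null(impute)) {
    impute <- apply(X, 2, function(col) stats::median(col, na.rm = TRUE))
  }
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- impute[[j]]
  }
  X
}
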
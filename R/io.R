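# Signal and configuration I/O. CSV is the canonical interchange format:
# signals as `time_s,value` (or a single column plus a declared sampling
# rate), annotations and feature tables as plain CSV, pipeline
# configuration as YAML, fitted models as JSON. All sample indices in
# files are 0-based and all times are in seconds.

#' Read a pressure signal from CSV
#'
#' Accepts either a two-column `time_s,value` file (sampling rate inferred
#' from the median timestamp step, uniformity enforced) or a single-column
#' file with `fs` supplied by the caller.
#'
#' @param path CSV path.
#' @param fs Sampling rate in Hz, required for single-column files.
#' @param max_jitter Maximum tolerated timestamp deviation from the uniform
#'   grid, as a fraction of the sample period (default 0.1).
#' @return A [raw_record].
#' @export
read_signal <- function(path, fs = NULL, max_jitter = 0.1) {
  df <- utils::read.csv(path)
  if (ncol(df) >= 2 && all(c("time_s", "value") %in% names(df))) {
    tm <- df$time_s
    dt <- diff(tm)
    period <- stats::median(dt)
    if (period <= 0) stop("non-increasing timestamps in ", path, call. = FALSE)
    bad <- which(abs(dt - period) > max_jitter * period)
    if (length(bad)) {
      stop("irregular sampling in ", path, " at rows ",
           paste(utils::head(bad + 1, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    }
    raw_record(df$value, fs = 1 / period, meta = list(path = path))
  } else if (ncol(df) == 1) {
    if (is.null(fs)) stop("single-column signal needs an explicit fs",
                          call. = FALSE)
    raw_record(df[[1]], fs = fs, meta = list(path = path))
  } else {
    stop("unrecognized signal layout in ", path,
         " (expected time_s,value or a single column)", call. = FALSE)
  }
}

#' Write a pressure signal to CSV (`time_s,value`)
#'
#' @param record A [raw_record] (or numeric vector with `fs`).
#' @param path Output path.
#' @param fs Sampling rate when `record` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_signal <- function(record, path, fs = NULL) {
  rec <- as_raw_record(record, fs = fs)
  df <- data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
                   value = rec$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Defaults mirror the pipeline's nominal operating point: 50 Hz sampling,
# DB5 at 5 levels, USH 0.02, DSH 0.22 s / 220 ms refractory, close-peak
# factor 0.4, missed-peak factor 1.66, decision threshold 0.5.
.default_config <- function() {
  list(
    sampling = list(fs = 50),
    wavelet = list(name = "db5", levels = 5, include_d5_resp = FALSE,
                   threshold_levels = 1, detrend = "mean"),
    detector = list(ush = 0.02, bias = 0, dsh = 0.22, refractory_ms = 220,
                    low_factor = 0.4, high_factor = 1.66,
                    threshold_relax = 0.5),
    feature = list(prominence_frac = 0.25, min_period_s = 1,
                   max_period_s = 15, template_n = 64, inhale_frac = 0.4,
                   cv_reciprocal = FALSE),
    classifier = list(threshold = 0.5, method = "newton"),
    output = list(digits = 10)
  )
}

#' Load, validate and default-fill a pipeline configuration
#'
#' Configuration is YAML with sections `sampling`, `wavelet`, `detector`,
#' `feature`, `classifier`, `output`. Unknown sections or keys are
#' rejected; missing keys take the package defaults.
#'
#' @param path YAML path, or `NULL` for the pure defaults.
#' @param overrides Optional named list merged over the file contents.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(user, overrides)) {
    if (length(src) == 0) next
    bad <- setdiff(names(src), names(cfg))
    if (length(bad)) stop("unknown config section(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (sec in names(src)) {
      badk <- setdiff(names(src[[sec]]), names(cfg[[sec]]))
      if (length(badk)) stop("unknown key(s) in '", sec, "': ",
                             paste(badk, collapse = ", "), call. = FALSE)
      cfg[[sec]][names(src[[sec]])] <- src[[sec]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
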
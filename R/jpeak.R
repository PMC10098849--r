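# J-peak detection on the separated BCG channel: amplitude-threshold
# candidate search with a 220 ms refractory window, then the interval-based
# correction rules (close-peak rejection below 0.4 x mean JJ interval,
# gap re-search above 1.66 x mean JJ with a relaxed threshold, unresolved
# gaps flagged as arrhythmia).

#' Detector parameters for J-peak search and correction
#'
#' @param ush_base Amplitude threshold base on the unit-maximum-normalized
#'   channel (default 0.02).
#' @param bias Fixed offset added to `ush_base`. Ignored when
#'   `adaptive_bias = TRUE` (the default), in which case the offset is
#'   0.3 x (90th-percentile height of the refractory-accepted candidates
#'   minus `ush_base`): the base threshold admits everything above the
#'   noise floor and the adaptive offset then anchors the working
#'   threshold to the J-peak amplitude mode, rejecting the low-amplitude
#'   skirts that band-limited reconstruction leaves around each beat.
#' @param dsh Minimum peak-to-peak interval in seconds (default 0.22).
#' @param refractory_ms Ignore window after an accepted J-peak, milliseconds
#'   (default 220; equals `dsh` at 50 Hz, both are enforced).
#' @param low_factor Adjacent peaks closer than `low_factor` x mean JJ
#'   interval are treated as false detections (default 0.4).
#' @param high_factor Gaps wider than `high_factor` x mean JJ interval are
#'   treated as missed beats (default 1.66).
#' @param threshold_relax Multiplicative threshold relaxation used when
#'   re-searching a gap (default 0.5, one relaxation round per gap).
#' @param adaptive_bias Logical, enable the adaptive bias rule.
#' @return Object of class `detector_params`.
#' @export
detector_params <- function(ush_base = 0.02, bias = 0, dsh = 0.22,
                            refractory_ms = 220, low_factor = 0.4,
                            high_factor = 1.66, threshold_relax = 0.5,
                            adaptive_bias = TRUE) {
  stopifnot(dsh > 0, refractory_ms > 0,
            low_factor > 0, low_factor < 1, high_factor > 1,
            threshold_relax > 0, threshold_relax <= 1)
  structure(list(ush_base = ush_base, bias = bias, dsh = dsh,
                 refractory_ms = refractory_ms, low_factor = low_factor,
                 high_factor = high_factor, threshold_relax = threshold_relax,
                 adaptive_bias = adaptive_bias),
            class = "detector_params")
}

# Local maxima (1-based indices): strictly above the left neighbour, at
# least the right neighbour (ties resolve to the earlier sample).
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Threshold-and-refractory J-peak candidate search
#'
#' The channel is normalized to unit maximum, local maxima at or above the
#' amplitude threshold `ush_base + bias` become candidates, and candidates
#' are accepted greedily in descending amplitude order subject to the
#' refractory window (no two accepted peaks closer than `refractory_ms`,
#' nor closer than `dsh` seconds).
#'
#' @param bcg Numeric BCG channel.
#' @param fs Sampling rate, Hz.
#' @param params A [detector_params].
#' @return Sorted 0-based sample indices of accepted candidates.
#' @export
detect_candidates <- function(bcg, fs, params = detector_params()) {
  stopifnot(inherits(params, "detector_params"))
  mx <- max(bcg)
  if (!is.finite(mx) || mx <= 0) return(integer(0))
  x <- bcg / mx
  refr <- max(round(params$refractory_ms / 1000 * fs), round(params$dsh * fs))
  greedy <- function(peaks) {
    # greedy acceptance in descending amplitude order (ties: earlier wins),
    # each accepted peak opening a refractory ignore-window
    accepted <- integer(0)
    for (p in peaks[order(-x[peaks], peaks)]) {
      if (!length(accepted) || all(abs(accepted - p) >= refr)) {
        accepted <- c(accepted, p)
      }
    }
    sort(accepted)
  }
  peaks <- .local_maxima(x)
  peaks <- peaks[x[peaks] >= params$ush_base + params$bias]
  if (!length(peaks)) return(integer(0))
  if (params$adaptive_bias) {
    provisional <- greedy(peaks)
    bias <- 0.3 * (stats::quantile(x[provisional], 0.9, names = FALSE) -
                     params$ush_base)
    peaks <- peaks[x[peaks] >= params$ush_base + max(bias, params$bias)]
    if (!length(peaks)) return(integer(0))
  }
  greedy(peaks) - 1L
}

#' Interval-based correction of J-peak candidates
#'
#' Applies, in order: (a) the mean JJ interval of the current window is
#' computed; (b) adjacent peaks closer than `low_factor` x mean JJ lose the
#' smaller-amplitude member (earlier peak kept on ties); (c) gaps wider
#' than `high_factor` x mean JJ are re-searched once with the amplitude
#' threshold relaxed by `threshold_relax`; (d) gaps still unresolved are
#' recorded as arrhythmia.
#'
#' @param candidates Sorted 0-based candidate indices.
#' @param bcg Numeric BCG channel (used for amplitudes and re-search).
#' @param fs Sampling rate, Hz.
#' @param params A [detector_params].
#' @return Object of class `jpeak_result`: `peaks` (0-based, sorted),
#'   `mean_jj` (samples; `NA` when fewer than 2 peaks), `removed`,
#'   `recovered`, `arrhythmia_gaps` (two-column matrix of gap bounds).
#' @export
correct_peaks <- function(candidates, bcg, fs, params = detector_params()) {
  stopifnot(inherits(params, "detector_params"))
  peaks <- sort(as.integer(candidates))
  removed <- integer(0)
  recovered <- integer(0)
  gaps <- matrix(integer(0), ncol = 2,
                 dimnames = list(NULL, c("from", "to")))
  if (length(peaks) < 2) {
    return(structure(list(peaks = peaks, mean_jj = NA_real_,
                          removed = removed, recovered = recovered,
                          arrhythmia_gaps = gaps),
                     class = "jpeak_result"))
  }
  mx <- max(bcg)
  x <- if (mx > 0) bcg / mx else bcg
  amp <- function(p) x[p + 1L]
  ## (b) close-peak rejection: drop the smaller of each too-close pair,
  ## iterated with the mean JJ interval recomputed until a fixed point
  repeat {
    mean_jj <- mean(diff(peaks))
    d <- diff(peaks)
    bad <- which(d < params$low_factor * mean_jj)
    if (!length(bad)) break
    i <- bad[1]
    drop_i <- if (amp(peaks[i + 1]) > amp(peaks[i])) i else i + 1L
    removed <- c(removed, peaks[drop_i])
    peaks <- peaks[-drop_i]
    if (length(peaks) < 2) break
  }

  ## (c) gap re-search with relaxed threshold
  if (length(peaks) >= 2) {
    refr <- max(round(params$refractory_ms / 1000 * fs),
                round(params$dsh * fs))
    bias <- if (params$adaptive_bias) {
      max(params$bias,
          0.3 * (stats::quantile(amp(peaks), 0.9, names = FALSE) -
                   params$ush_base))
    } else params$bias
    thr <- (params$ush_base + bias) * params$threshold_relax
    d <- diff(peaks)
    wide <- which(d > params$high_factor * mean_jj)
    for (i in wide) {
      lo <- peaks[i] + refr
      hi <- peaks[i + 1] - refr
      if (hi <= lo) {
        gaps <- rbind(gaps, c(peaks[i], peaks[i + 1]))
        next
      }
      seg <- x[(lo + 1L):(hi + 1L)]
      loc <- .local_maxima(seg)
      loc <- loc[seg[loc] >= thr]
      if (length(loc)) {
        found <- lo + loc[which.max(seg[loc])] - 1L
        recovered <- c(recovered, found)
      } else {
        gaps <- rbind(gaps, c(peaks[i], peaks[i + 1]))
      }
    }
    if (length(recovered)) peaks <- sort(c(peaks, recovered))
  }

  structure(list(peaks = peaks,
                 mean_jj = if (length(peaks) >= 2) mean(diff(peaks)) else NA_real_,
                 removed = removed, recovered = recovered,
                 arrhythmia_gaps = gaps),
            class = "jpeak_result")
}

#' Detect and correct J-peaks in a BCG channel
#'
#' Composition of [detect_candidates()] and [correct_peaks()].
#'
#' @inheritParams detect_candidates
#' @return A `jpeak_result` (see [correct_peaks()]).
#' @export
detect_jpeaks <- function(bcg, fs, params = detector_params()) {
  correct_peaks(detect_candidates(bcg, fs, params), bcg, fs, params)
}

#' @export
print.jpeak_result <- function(x, ...) {
  cat("<jpeak_result> ", length(x$peaks), " peaks, mean JJ = ",
      if (is.na(x$mean_jj)) "NA" else sprintf("%.1f samples", x$mean_jj),
      "; removed ", length(x$removed), ", recovered ", length(x$recovered),
      ", arrhythmia gaps ", nrow(x$arrhythmia_gaps), "\n", sep = "")
  invisible(x)
}
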
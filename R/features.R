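# Per-breath feature extraction: trough-to-trough segmentation of the
# respiration channel, heart-rate-variability statistics over the J-peaks
# falling inside each frame (AVNN, SDNN, CV), the breath period, and the
# waveform-similarity statistic xi -- the maximum cross-correlation of the
# frame with a standard breath template, normalized by the template's
# maximum autocorrelation, in percent.

#' Prominence-filtered local minima (trough detection)
#'
#' A trough's prominence is the smaller of the climbs from the trough to
#' the highest point reachable on either side before meeting a deeper
#' trough.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence to retain a trough.
#' @param min_distance Minimum spacing between retained troughs, samples.
#' @return 1-based indices of retained troughs.
#' @keywords internal
find_troughs <- function(x, min_prominence, min_distance = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[x[i] < x[i - 1] & x[i] <= x[i + 1]]
  # boundary troughs: a record that starts or ends mid-descent into a
  # trough still bounds a usable frame (one-sided prominence applies)
  if (x[1] < x[2]) cand <- c(1L, cand)
  if (x[n] < x[n - 1]) cand <- c(cand, n)
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    v <- x[p]
    peak_l <- if (p == 1L) Inf else {
      left <- x[seq_len(p - 1)]
      lower_l <- which(left < v)
      if (length(lower_l)) max(left[(max(lower_l) + 1):(p - 1)]) else max(left)
    }
    peak_r <- if (p == n) Inf else {
      right <- x[(p + 1):n]
      lower_r <- which(right < v)
      if (length(lower_r)) max(right[seq_len(min(lower_r) - 1)]) else max(right)
    }
    min(peak_l, peak_r) - v
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce min spacing, deepest troughs win
  ord <- keep[order(x[keep], keep)]
  sel <- integer(0)
  for (p in ord) {
    if (!length(sel) || all(abs(sel - p) >= min_distance)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Segment a respiration channel into breath frames
#'
#' Frames are half-open trough-to-trough slices. Troughs are local minima
#' with prominence at least `prominence_frac` of the channel's robust
#' amplitude (5th-95th percentile range) and at least `min_period_s` apart.
#' Frames longer than `max_period_s` (sustained apnea) are split into equal
#' sub-frames no longer than `max_period_s` and flagged; if no troughs are
#' found at all, fixed 5 s frames are emitted, all flagged.
#'
#' @param respiration Separated, DC-removed respiration channel.
#' @param fs Sampling rate, Hz.
#' @param prominence_frac Trough prominence threshold as a fraction of the
#'   robust channel amplitude (default 0.25).
#' @param min_period_s,max_period_s Admissible breath-period bounds in
#'   seconds (defaults 1 and 15, i.e. 4-60 breaths/min).
#' @return Data frame of class `breath_frames` with 0-based columns
#'   `start_sample`, `end_sample` and logical `flagged` (frame did not come
#'   from two bounding troughs).
#' @export
segment_breath_frames <- function(respiration, fs, prominence_frac = 0.25,
                                  min_period_s = 1, max_period_s = 15) {
  n <- length(respiration)
  amp <- diff(stats::quantile(respiration, c(0.05, 0.95), names = FALSE))
  troughs <- if (amp > 0) {
    find_troughs(respiration, min_prominence = prominence_frac * amp,
                 min_distance = max(1L, round(min_period_s * fs)))
  } else integer(0)

  if (length(troughs) < 2) {
    # degenerate channel: fixed-length fallback frames
    step <- round(5 * fs)
    starts <- seq.int(0L, max(0L, n - step), by = step)
    frames <- data.frame(start_sample = starts,
                         end_sample = pmin(starts + step, n),
                         flagged = TRUE)
    frames <- frames[frames$end_sample - frames$start_sample >=
                       round(min_period_s * fs), , drop = FALSE]
    class(frames) <- c("breath_frames", class(frames))
    return(frames)
  }

  starts <- troughs[-length(troughs)] - 1L # to 0-based
  ends <- troughs[-1] - 1L
  out <- list()
  max_len <- round(max_period_s * fs)
  for (i in seq_along(starts)) {
    len <- ends[i] - starts[i]
    if (len <= max_len) {
      out[[length(out) + 1]] <- data.frame(start_sample = starts[i],
                                           end_sample = ends[i],
                                           flagged = FALSE)
    } else {
      k <- ceiling(len / max_len)
      bounds <- round(seq(starts[i], ends[i], length.out = k + 1))
      out[[length(out) + 1]] <- data.frame(start_sample = bounds[-(k + 1)],
                                           end_sample = bounds[-1],
                                           flagged = TRUE)
    }
  }
  frames <- do.call(rbind, out)
  keep <- frames$end_sample - frames$start_sample >= round(min_period_s * fs)
  frames <- frames[keep, , drop = FALSE]
  rownames(frames) <- NULL
  class(frames) <- c("breath_frames", class(frames))
  frames
}

# J-peak indices (0-based) falling inside a half-open frame.
.peaks_in_frame <- function(peaks, start_sample, end_sample) {
  peaks[peaks >= start_sample & peaks < end_sample]
}

#' Mean NN interval within a breath frame
#'
#' Mean of adjacent J-peak intervals divided by the sampling rate, seconds.
#'
#' @param peaks Sorted 0-based J-peak sample indices inside the frame.
#' @param fs Sampling rate, Hz.
#' @return Seconds; `NA` when fewer than two peaks.
#' @export
avnn <- function(peaks, fs) {
  if (length(peaks) < 2) return(NA_real_)
  mean(diff(peaks)) / fs
}

#' Standard deviation of NN intervals within a breath frame
#'
#' Sample standard deviation (n-1 denominator) of the adjacent J-peak
#' intervals in seconds; a single interval yields 0.
#'
#' @inheritParams avnn
#' @return Seconds; `NA` when fewer than two peaks.
#' @export
sdnn <- function(peaks, fs) {
  if (length(peaks) < 2) return(NA_real_)
  ivl <- diff(peaks) / fs
  if (length(ivl) == 1) return(0)
  stats::sd(ivl)
}

#' Coefficient of variation of NN intervals
#'
#' Defaults to SDNN / AVNN (the ratio of interval variability to the mean
#' interval); `reciprocal = TRUE` returns AVNN / SDNN instead.
#'
#' @param avnn_s Mean NN interval, seconds.
#' @param sdnn_s SD of NN intervals, seconds.
#' @param reciprocal Use the inverted ratio.
#' @return Dimensionless; `NA` when undefined.
#' @export
cv_nn <- function(avnn_s, sdnn_s, reciprocal = FALSE) {
  if (is.na(avnn_s) || is.na(sdnn_s)) return(NA_real_)
  if (reciprocal) {
    if (sdnn_s == 0) return(NA_real_)
    return(avnn_s / sdnn_s)
  }
  if (avnn_s <= 0) return(NA_real_)
  sdnn_s / avnn_s
}

#' Breath period of a frame
#'
#' Number of samples in the frame divided by the sampling rate.
#'
#' @param start_sample,end_sample Half-open 0-based frame bounds.
#' @param fs Sampling rate, Hz.
#' @return Seconds.
#' @export
breath_period <- function(start_sample, end_sample, fs) {
  (end_sample - start_sample) / fs
}

#' Full cross-correlation of two real sequences
#'
#' \eqn{R_{f,g}(n) = \sum_k f_k \, g_{k+n}} over every lag with any
#' overlap, i.e. \eqn{n = -(\mathrm{len}(g)-1), \dots, \mathrm{len}(f)-1},
#' zero-padded outside support. Sums are accumulated directly (no FFT), so
#' integer inputs give exact integer results.
#'
#' @param f,g Non-empty numeric sequences.
#' @return List with `lag` and `value`, both of length
#'   `length(f) + length(g) - 1`.
#' @export
cross_correlation <- function(f, g) {
  nf <- length(f); ng <- length(g)
  if (nf == 0 || ng == 0) stop("empty input", call. = FALSE)
  lags <- seq.int(-(ng - 1L), nf - 1L)
  val <- vapply(lags, function(n) {
    lo <- max(1L, 1L - n)       # indices of f with g[k + n] in range
    hi <- min(nf, ng - n)
    if (lo > hi) return(0)
    k <- lo:hi
    sum(f[k] * g[k + n])
  }, numeric(1))
  list(lag = lags, value = val)
}

#' Standard breath template
#'
#' One normalized normal-breath cycle used as the reference waveform for
#' the similarity statistic: a raised-cosine cycle (trough to trough, peak
#' at end-expiration), zero-mean and unit-energy. A user template may be
#' supplied as a numeric vector and is normalized the same way.
#'
#' @param n Number of samples.
#' @param inhale_frac Fraction of the cycle spent inhaling (default 0.4,
#'   matching the synthetic generator's normal preset).
#' @param waveform Optional user-supplied cycle to normalize instead.
#' @return Object of class `standard_template` (numeric waveform with an
#'   `origin` attribute).
#' @export
standard_template <- function(n = 64, inhale_frac = 0.4, waveform = NULL) {
  if (is.null(waveform)) {
    phase <- (seq_len(n) - 1) / n
    w <- .breath_cycle(phase, inhale_frac)
    origin <- "builtin"
  } else {
    w <- as.numeric(waveform)
    origin <- "user"
  }
  w <- w - mean(w)
  e <- sqrt(sum(w^2))
  if (e == 0) stop("degenerate template (zero energy)", call. = FALSE)
  structure(w / e, class = "standard_template", origin = origin)
}

# Linear resampling to m samples.
.resample <- function(w, m) {
  if (length(w) == m) return(as.numeric(w))
  stats::approx(seq(0, 1, length.out = length(w)), as.numeric(w),
                xout = seq(0, 1, length.out = m))$y
}

#' Waveform similarity of a breath frame against the standard template
#'
#' The template is resampled to the frame length; both sequences are
#' normalized to zero mean and unit energy; the statistic is
#' \eqn{\xi = \max_n R_{f,g}(n) / \max_n R_{f,f}(n) \times 100}, clamped
#' below at 0. With unit-energy normalization \eqn{\max R_{f,f} = 1} and
#' \eqn{\xi \le 100} by the Cauchy-Schwarz inequality.
#'
#' @param frame_wave Numeric respiration slice of one breath frame,
#'   length >= 4.
#' @param template A [standard_template] (resampled internally).
#' @return Similarity in percent, in `[0, 100]`; a zero-energy frame gives 0.
#' @export
similarity <- function(frame_wave, template = standard_template()) {
  m <- length(frame_wave)
  if (m < 4) stop("frame too short for similarity (need >= 4 samples)",
                  call. = FALSE)
  f <- .resample(unclass(template), m)
  f <- f - mean(f)
  ef <- sqrt(sum(f^2))
  if (ef == 0) return(0)
  f <- f / ef
  g <- frame_wave - mean(frame_wave)
  eg <- sqrt(sum(g^2))
  if (eg == 0) return(0)
  g <- g / eg
  rfg <- max(cross_correlation(f, g)$value)
  rff <- max(cross_correlation(f, f)$value)
  max(0, rfg / rff * 100)
}

#' Extract the per-frame feature vector
#'
#' @param frame_wave Respiration slice of the frame.
#' @param peaks 0-based J-peak samples inside the frame.
#' @param start_sample,end_sample Frame bounds (0-based, half-open).
#' @param fs Sampling rate, Hz.
#' @param template Standard breath template for the similarity statistic.
#' @param cv_reciprocal Use AVNN/SDNN instead of SDNN/AVNN for CV.
#' @return One-row data frame: `frame_start`, `frame_end`, `avnn_s`,
#'   `sdnn_s`, `cv`, `ti_s`, `n_beats`, `similarity_pct`. HRV features are
#'   `NA` when fewer than two beats fall inside the frame.
#' @export
extract_features <- function(frame_wave, peaks, start_sample, end_sample, fs,
                             template = standard_template(),
                             cv_reciprocal = FALSE) {
  a <- avnn(peaks, fs)
  s <- sdnn(peaks, fs)
  data.frame(
    frame_start = start_sample, frame_end = end_sample,
    avnn_s = a, sdnn_s = s, cv = cv_nn(a, s, reciprocal = cv_reciprocal),
    ti_s = breath_period(start_sample, end_sample, fs),
    n_beats = length(peaks),
    similarity_pct = similarity(frame_wave, template))
}

#' Feature table for a whole recording
#'
#' Applies [extract_features()] to every segmented frame.
#'
#' @param separated A `separated_signals` object (from [separate()]).
#' @param jpeaks A `jpeak_result` (from [detect_jpeaks()]).
#' @param frames Optional `breath_frames`; segmented from the respiration
#'   channel when omitted.
#' @param template Standard breath template.
#' @param cv_reciprocal Use AVNN/SDNN for CV.
#' @return Data frame with one row per frame, columns as in
#'   [extract_features()] plus `flagged`.
#' @export
feature_table <- function(separated, jpeaks, frames = NULL,
                          template = standard_template(),
                          cv_reciprocal = FALSE) {
  stopifnot(inherits(separated, "separated_signals"))
  if (is.null(frames)) {
    frames <- segment_breath_frames(separated$respiration, separated$fs)
  }
  peaks <- if (inherits(jpeaks, "jpeak_result")) jpeaks$peaks else jpeaks
  rows <- lapply(seq_len(nrow(frames)), function(i) {
    fr <- frames[i, ]
    wave <- separated$respiration[(fr$start_sample + 1L):fr$end_sample]
    extract_features(wave,
                     .peaks_in_frame(peaks, fr$start_sample, fr$end_sample),
                     fr$start_sample, fr$end_sample, separated$fs,
                     template = template, cv_reciprocal = cv_reciprocal)
  })
  out <- do.call(rbind, rows)
  out$flagged <- frames$flagged
  out
}
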
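# Wavelet band separation: decompose the bed-pressure channel with a
# 5-level DB5 transform, soft-threshold the noisiest detail level, and
# reconstruct respiration (approximation band) and BCG (detail bands 1-3)
# as aligned, full-length channels.

#' Dyadic frequency band of a wavelet decomposition level
#'
#' Detail level \eqn{j} of a dyadic wavelet decomposition at sampling rate
#' \eqn{f_s} carries the band \eqn{(f_s/2^{j+1}, f_s/2^j)} Hz; the level-\eqn{j}
#' approximation carries \eqn{(0, f_s/2^{j+1})}. At 50 Hz and 5 levels this
#' yields D1 12.5-25, D2 6.25-12.5, D3 3.125-6.25, D4 1.5625-3.125,
#' D5 0.78125-1.5625 and A5 0-0.78125 Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param level Decomposition level, 1..10.
#' @param kind `"detail"` or `"approx"`.
#' @return Numeric vector `c(lo, hi)` in Hz.
#' @examples
#' band_edges(50, 1, "detail")  # 12.5 - 25 Hz
#' band_edges(50, 5, "approx")  # 0 - 0.78125 Hz
#' @export
band_edges <- function(fs, level, kind = c("detail", "approx")) {
  kind <- match.arg(kind)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!is.numeric(level) || level < 1 || level > 10 || level != round(level)) {
    stop("level must be an integer in 1..10", call. = FALSE)
  }
  hi <- fs / 2^level
  lo <- fs / 2^(level + 1)
  if (kind == "detail") c(lo = lo, hi = hi) else c(lo = 0, hi = lo)
}

#' Multi-level discrete wavelet decomposition of a pressure record
#'
#' @param record A [raw_record] (or bare numeric vector, in which case `fs`
#'   must be supplied via `attr` or defaults to 50).
#' @param wavelet Wavelet identifier, default `"db5"`.
#' @param levels Number of decomposition levels, default 5.
#' @return An object of class `wavelet_decomposition`: detail coefficient
#'   vectors `details[[1]]`..`details[[levels]]` (D1..D5), approximation
#'   `approx` (A5), `original_length`, `fs`, and bookkeeping needed for
#'   exact inversion via [reconstruct()].
#' @export
decompose <- function(record, wavelet = "db5", levels = 5L) {
  rec <- as_raw_record(record)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  n <- length(rec$samples)
  if (n < 2^levels) {
    stop("signal too short for ", levels, "-level decomposition (length ", n,
         " < ", 2^levels, ")", call. = FALSE)
  }
  dec <- .wavedec(rec$samples, wavelet = wavelet, levels = as.integer(levels))
  structure(
    list(wavelet_name = wavelet, levels = as.integer(levels),
         details = dec$details, approx = dec$approx, lens = dec$lens,
         original_length = n, fs = rec$fs),
    class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat("<wavelet_decomposition> ", x$wavelet_name, ", ", x$levels,
      " levels, n = ", x$original_length, ", fs = ", x$fs, " Hz\n", sep = "")
  for (j in seq_len(x$levels)) {
    be <- band_edges(x$fs, j, "detail")
    cat(sprintf("  D%d: %d coefficients, %.5g-%.5g Hz\n", j,
                length(x$details[[j]]), be[1], be[2]))
  }
  be <- band_edges(x$fs, x$levels, "approx")
  cat(sprintf("  A%d: %d coefficients, 0-%.5g Hz\n", x$levels,
              length(x$approx), be[2]))
  invisible(x)
}

#' Inverse wavelet transform, optionally restricted to selected bands
#'
#' Linearity of the inverse transform makes single-band reconstructions
#' additive: the sum over all `levels` detail bands plus the approximation
#' equals the original signal to floating-point precision.
#'
#' @param decomp A `wavelet_decomposition`.
#' @param keep_details Integer vector of detail levels to retain (others are
#'   zeroed). `NULL` keeps all.
#' @param keep_approx Logical, retain the approximation band.
#' @return Numeric vector of length `original_length`.
#' @export
reconstruct <- function(decomp, keep_details = NULL, keep_approx = TRUE) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  details <- decomp$details
  if (!is.null(keep_details)) {
    for (j in seq_len(decomp$levels)) {
      if (!(j %in% keep_details)) details[[j]] <- numeric(length(details[[j]]))
    }
  }
  approx <- if (keep_approx) decomp$approx else numeric(length(decomp$approx))
  .waverec(list(details = details, approx = approx, lens = decomp$lens,
                wavelet = decomp$wavelet_name, levels = decomp$levels))
}

#' Soft thresholding of wavelet coefficients
#'
#' Shrinkage rule \eqn{c \mapsto \mathrm{sign}(c)\,\max(|c|-\lambda, 0)}.
#'
#' @param coeffs Numeric vector of coefficients.
#' @param lam Threshold \eqn{\lambda \ge 0}.
#' @return Thresholded coefficients, same length.
#' @export
soft_threshold <- function(coeffs, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0) {
    stop("lam must be a single non-negative number", call. = FALSE)
  }
  sign(coeffs) * pmax(abs(coeffs) - lam, 0)
}

#' Universal threshold estimate from the finest detail level
#'
#' Noise scale is estimated robustly as
#' \eqn{\hat\sigma = \mathrm{median}(|D_j|)/0.6745} (the median absolute
#' deviation of a zero-mean Gaussian), and the threshold is the universal
#' rule \eqn{\lambda = \hat\sigma\sqrt{2\ln N}} with \eqn{N} the original
#' signal length.
#'
#' @param decomp A `wavelet_decomposition`.
#' @param level Detail level whose coefficients estimate the noise scale
#'   (default 1, the band dominated by broadband noise).
#' @return Threshold \eqn{\lambda \ge 0}.
#' @export
estimate_lambda <- function(decomp, level = 1L) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  d <- decomp$details[[level]]
  if (length(d) == 0) stop("empty detail level", call. = FALSE)
  sigma <- stats::median(abs(d)) / 0.6745
  sigma * sqrt(2 * log(decomp$original_length))
}

#' Separate respiration and BCG channels by wavelet band reconstruction
#'
#' The record is decomposed (DB5, 5 levels by default). Respiration is the
#' reconstruction of the approximation band alone (optionally including the
#' coarsest detail band), with the channel mean subtracted to remove the DC
#' baseline. BCG is the reconstruction of detail levels 1-3 after soft
#' thresholding the selected levels (level 1 by default) at the universal
#' threshold. For sampling rates other than 50 Hz the band plan is
#' recomputed from [band_edges()] so that respiration keeps 0-0.8 Hz and
#' BCG keeps roughly 3-15 Hz coverage.
#'
#' @param record A [raw_record].
#' @param wavelet Wavelet identifier, default `"db5"`.
#' @param levels Decomposition levels, default 5.
#' @param include_d5_resp Include the coarsest detail band in the
#'   respiration reconstruction (default `FALSE`).
#' @param threshold_levels Detail levels to soft-threshold before the BCG
#'   reconstruction, default `1`.
#' @param detrend `"mean"` (default) or `"linear"` baseline removal for the
#'   respiration channel.
#' @return An object of class `separated_signals` with elements
#'   `respiration`, `bcg` (numeric, same length and fs as the input), `fs`,
#'   `band_plan` and `threshold_used`.
#' @export
separate <- function(record, wavelet = "db5", levels = 5L,
                     include_d5_resp = FALSE, threshold_levels = 1L,
                     detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  rec <- as_raw_record(record)
  fs <- rec$fs
  n <- length(rec$samples)
  if (fs != 50) {
    # keep respiration below ~0.8 Hz: smallest level count whose approx band
    # top edge is <= 0.8 Hz (capped at 10)
    levels <- max(levels, min(10L, ceiling(log2(fs / 0.8)) - 1L))
  }
  breaths_needed <- 2 / 0.2 # two breath periods at the slowest normal rate
  if (n / fs < breaths_needed) {
    warning("record shorter than two breath periods; separation may be unstable")
  }
  decomp <- decompose(rec, wavelet = wavelet, levels = levels)

  # BCG plan: detail levels lying wholly above ~3 Hz (levels 1-3 at 50 Hz);
  # the small tolerance keeps the 3.125 Hz edge of the third band in.
  bcg_levels <- which(vapply(seq_len(levels), function(j) {
    band_edges(fs, j, "detail")[1] >= 2.8
  }, logical(1)))
  if (length(bcg_levels) == 0) bcg_levels <- 1L

  lam <- vapply(seq_len(levels), function(j) {
    if (j %in% threshold_levels) estimate_lambda(decomp, level = j) else 0
  }, numeric(1))
  den <- decomp
  for (j in intersect(threshold_levels, seq_len(levels))) {
    den$details[[j]] <- soft_threshold(den$details[[j]], lam[j])
  }
  bcg <- reconstruct(den, keep_details = bcg_levels, keep_approx = FALSE)

  resp_details <- if (include_d5_resp) levels else integer(0)
  resp <- reconstruct(decomp, keep_details = resp_details, keep_approx = TRUE)
  resp <- if (detrend == "mean") {
    resp - mean(resp)
  } else {
    stats::residuals(stats::lm.fit(cbind(1, seq_along(resp)), resp))
  }

  structure(
    list(respiration = as.numeric(resp), bcg = as.numeric(bcg), fs = fs,
         band_plan = list(respiration = list(approx = levels,
                                             details = resp_details),
                          bcg = list(details = bcg_levels)),
         threshold_used = lam),
    class = "separated_signals")
}

#' @export
print.separated_signals <- function(x, ...) {
  cat("<separated_signals> n =", length(x$respiration), "fs =", x$fs, "Hz\n")
  cat("  respiration: A", x$band_plan$respiration$approx,
      if (length(x$band_plan$respiration$details))
        paste0(" + D", paste(x$band_plan$respiration$details, collapse = ",D")),
      "\n", sep = "")
  cat("  bcg: D", paste(x$band_plan$bcg$details, collapse = ",D"),
      " (soft threshold ",
      paste(sprintf("%.4g", x$threshold_used[x$threshold_used > 0]),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' One-sided magnitude spectrum
#'
#' @param channel Numeric vector, length >= 8.
#' @param fs Sampling rate in Hz.
#' @return List with `frequency` (Hz) and `magnitude` (|FFT|, one-sided).
#' @export
spectrum_mag <- function(channel, fs) {
  n <- length(channel)
  if (n < 8) stop("channel too short for a spectrum (need >= 8 samples)",
                  call. = FALSE)
  ft <- stats::fft(channel)
  nh <- floor(n / 2) + 1L
  list(frequency = (seq_len(nh) - 1) * fs / n,
       magnitude = Mod(ft[seq_len(nh)]))
}

#' Dominant spectral frequency above a floor
#'
#' @param channel Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param fmin Lower edge of the search band (Hz); the DC bin is excluded
#'   whenever `fmin > 0`.
#' @return Frequency (Hz) of the largest magnitude-spectrum bin at or above
#'   `fmin`.
#' @export
dominant_frequency <- function(channel, fs, fmin = 0) {
  if (fmin >= fs / 2) stop("fmin must be below the Nyquist frequency",
                           call. = FALSE)
  sp <- spectrum_mag(channel, fs)
  keep <- sp$frequency >= fmin
  if (!any(keep)) stop("empty search band", call. = FALSE)
  sp$frequency[keep][which.max(sp$magnitude[keep])]
}
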
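# Synthetic bed-pressure generator. Emits a single-channel recording as the
# additive mixture f(t) = DC + respiration + BCG pulse train + motion
# artifacts + Gaussian noise, together with exact ground truth (J-peak
# samples, breath troughs, per-frame labels, clean component channels) so
# every downstream stage can be tested without hardware recordings.

#' Construct a raw pressure record
#'
#' @param samples Numeric amplitude sequence (arbitrary units), length >= 2.
#' @param fs Sampling rate in Hz.
#' @param meta Optional named list of provenance information.
#' @return Object of class `raw_record`.
#' @export
raw_record <- function(samples, fs, meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("record needs at least 2 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, meta = meta),
            class = "raw_record")
}

#' @rdname raw_record
#' @param x Object to coerce: a `raw_record` is passed through; a numeric
#'   vector is wrapped (its `fs` attribute is honoured, else 50 Hz).
#' @export
as_raw_record <- function(x, fs = NULL) {
  if (inherits(x, "raw_record")) return(x)
  if (is.numeric(x)) {
    return(raw_record(x, fs = fs %||% attr(x, "fs") %||% 50))
  }
  stop("cannot coerce to raw_record", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.raw_record <- function(x, ...) {
  cat("<raw_record> ", length(x$samples), " samples @ ", x$fs, " Hz (",
      sprintf("%.1f", length(x$samples) / x$fs), " s)\n", sep = "")
  invisible(x)
}

#' Synthetic recording configuration
#'
#' Defaults describe a normal adult asleep on the mattress: respiration in
#' the 0.2-0.4 Hz band, heart rate 70 beats/min, BCG pulse amplitude half
#' the breathing excursion.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, seconds.
#' @param hr_bpm Mean heart rate, beats per minute.
#' @param hr_jitter Standard deviation of the beat-to-beat interval, seconds.
#' @param breath_rate_hz Respiration frequency, Hz (0.2-0.4 for normal
#'   presets).
#' @param breath_amp,bcg_amp Relative amplitudes (arbitrary units).
#' @param noise_sd Standard deviation of the additive Gaussian noise; when
#'   `snr_db` is given it is derived from the clean mixture instead.
#' @param snr_db Optional signal-to-noise ratio in dB; overrides `noise_sd`.
#' @param motion_events List of `c(start_s, duration_s, amplitude)` transient
#'   artifacts (exponentially decaying random transients), off by default.
#' @param apnea_events List of `list(start, duration, type)` with `type`
#'   one of `"post_inhalation"`, `"post_exhalation"`; events must lie within
#'   the recording and must not overlap.
#' @param apnea_residual Residual fraction of respiration amplitude during
#'   apnea (default 0.05, i.e. attenuation to 5 percent).
#' @param inhale_frac Fraction of the breath cycle spent inhaling (pressure
#'   falling from peak to trough); the cycle runs trough -> peak -> trough
#'   (end-inspiration is the trough, end-expiration the peak).
#' @param dc_offset Baseline level added to the mixture.
#' @param seed Integer RNG seed; identical config and seed reproduce the
#'   output bit for bit.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(fs = 50, duration = 60, hr_bpm = 70, hr_jitter = 0.02,
                         breath_rate_hz = 0.3, breath_amp = 1, bcg_amp = 0.5,
                         noise_sd = 0, snr_db = NULL, motion_events = list(),
                         apnea_events = list(), apnea_residual = 0.05,
                         inhale_frac = 0.4, dc_offset = 0, seed = 1L) {
  stopifnot(fs > 0, duration > 0, hr_bpm > 0, hr_jitter >= 0,
            breath_rate_hz > 0, breath_amp >= 0, bcg_amp >= 0,
            noise_sd >= 0, apnea_residual >= 0, apnea_residual < 1,
            inhale_frac > 0, inhale_frac < 1)
  apnea_events <- lapply(apnea_events, function(ev) {
    ev <- as.list(ev)
    names(ev) <- c("start", "duration", "type")[seq_along(ev)]
    if (is.null(ev$type)) ev$type <- "post_inhalation"
    ev$start <- as.numeric(ev$start); ev$duration <- as.numeric(ev$duration)
    if (!ev$type %in% c("post_inhalation", "post_exhalation")) {
      stop("apnea type must be post_inhalation or post_exhalation",
           call. = FALSE)
    }
    if (ev$start < 0 || ev$start + ev$duration > duration) {
      stop("apnea event outside the recording", call. = FALSE)
    }
    ev
  })
  if (length(apnea_events) > 1) {
    o <- order(vapply(apnea_events, `[[`, numeric(1), "start"))
    apnea_events <- apnea_events[o]
    for (i in seq_len(length(apnea_events) - 1)) {
      if (apnea_events[[i]]$start + apnea_events[[i]]$duration >
          apnea_events[[i + 1]]$start) {
        stop("apnea events overlap", call. = FALSE)
      }
    }
  }
  structure(list(fs = fs, duration = duration, hr_bpm = hr_bpm,
                 hr_jitter = hr_jitter, breath_rate_hz = breath_rate_hz,
                 breath_amp = breath_amp, bcg_amp = bcg_amp,
                 noise_sd = noise_sd, snr_db = snr_db,
                 motion_events = motion_events, apnea_events = apnea_events,
                 apnea_residual = apnea_residual, inhale_frac = inhale_frac,
                 dc_offset = dc_offset, seed = as.integer(seed)),
            class = "synth_config")
}

#' One-beat ballistocardiogram template
#'
#' A single cardiac cycle modelled as a sum of Gaussian-windowed lobes with
#' alternating signs, producing the canonical H, I, J, K, L, M, N extremum
#' sequence with J the dominant positive deflection. The template is
#' zero-mean (no DC leakage into the respiration band) and peak-normalized
#' to 1; its spectral energy sits in the 0.5-20 Hz BCG band (truncated at
#' the Nyquist frequency for low sampling rates).
#'
#' @param fs Sampling rate, Hz (>= 25).
#' @param beat_duration Length of the cardiac cycle, seconds, in (0.3, 1.2).
#' @return Numeric waveform of `round(fs * beat_duration)` samples.
#' @export
make_bcg_template <- function(fs, beat_duration) {
  if (fs < 25) stop("fs must be >= 25 Hz", call. = FALSE)
  if (beat_duration < 0.3 || beat_duration > 1.2) {
    stop("beat_duration must lie in [0.3, 1.2] s", call. = FALSE)
  }
  n <- max(8L, round(fs * beat_duration))
  w <- .bcg_wave((seq_len(n) - 1) / n)
  w <- w - mean(w)
  w / max(w)
}

# Continuous-time one-beat BCG waveform, evaluated at cycle phase in [0, 1).
# Lobe centres (cycle fraction), signed amplitudes, widths give the H, I, J,
# K, L, M, N extremum sequence; the complex occupies the first half of the
# cycle and the remainder is the quiet diastolic tail, as in recorded BCG
# beats. Negative lobe amplitudes are scaled so the pulse integrates to
# exactly zero: a pulse train built from it then has no spectral energy
# below the heart rate (the physiological BCG band starts near 0.5 Hz), so
# nothing leaks into the respiration band even with beat-interval jitter.
.bcg_lobes <- local({
  centre <- c(0.10, 0.16, 0.23, 0.30, 0.38, 0.46, 0.54)
  amp    <- c(0.30, -0.55, 1.00, -0.60, 0.38, -0.20, 0.12)
  width  <- c(0.028, 0.028, 0.032, 0.032, 0.038, 0.042, 0.048)
  area <- amp * width
  neg <- amp < 0
  amp[neg] <- amp[neg] * sum(area[!neg]) / -sum(area[neg])
  list(centre = centre, amp = amp, width = width)
})

.bcg_wave <- function(phase) {
  lb <- .bcg_lobes
  out <- numeric(length(phase))
  for (k in seq_along(lb$centre)) {
    out <- out + lb$amp[k] * exp(-0.5 * ((phase - lb$centre[k]) / lb$width[k])^2)
  }
  out
}

# Peak value and peak phase of the continuous waveform (fine-grid argmax,
# computed once).
.bcg_wave_peak <- local({
  ph <- seq(0, 1, by = 1e-4)
  v <- NULL # filled lazily; .bcg_wave is defined above at load time
  function() {
    if (is.null(v)) v <<- .bcg_wave(ph)
    list(phase = ph[which.max(v)], value = max(v))
  }
})

# Respiration cycle value at phase in [0,1): trough at phase 0
# (end-inspiration), peak at phase `1 - inhale_frac` (end-expiration),
# raised-cosine rise/fall, range [-0.5, 0.5].
.breath_cycle <- function(phase, inhale_frac) {
  a <- 1 - inhale_frac # exhale fraction: pressure rising trough -> peak
  v <- ifelse(phase < a,
              0.5 * (1 - cos(pi * phase / a)),
              0.5 * (1 + cos(pi * (phase - a) / (1 - a))))
  v - 0.5
}

#' Synthesize a bed-pressure recording with ground truth
#'
#' The emitted signal is the additive mixture of a DC baseline, a
#' raised-cosine respiration wave, a BCG pulse train, optional motion
#' transients and Gaussian noise. During apnea events the respiration
#' component is held at the end-inspiration (post-inhalation type) or
#' end-expiration (post-exhalation type) level with its oscillation
#' attenuated to `apnea_residual` of normal, while the cardiac pulse train
#' continues.
#'
#' @param config A [synth_config].
#' @return List with `record` (a [raw_record]) and `truth` (class
#'   `ground_truth`): `j_peak_samples`, `breath_trough_samples`,
#'   `frames` (data frame: `start_sample`, `end_sample`, `label`),
#'   `apnea_events` (data frame in samples), `clean_respiration`,
#'   `clean_bcg`, `noise`, `motion`. Sample indices are 0-based and event
#'   bounds half-open.
#' @export
synthesize <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  n <- round(cf$fs * cf$duration)
  t <- (seq_len(n) - 1) / cf$fs

  rng <- .local_rng(cf$seed)
  on.exit(rng$restore(), add = TRUE)

  ## respiration with apnea gating
  phase <- (t * cf$breath_rate_hz) %% 1
  resp_norm <- .breath_cycle(phase, cf$inhale_frac)
  resp <- resp_norm
  ev_samples <- data.frame(start_sample = integer(0), end_sample = integer(0),
                           type = character(0), stringsAsFactors = FALSE)
  for (ev in cf$apnea_events) {
    s0 <- floor(ev$start * cf$fs)
    s1 <- min(n, floor((ev$start + ev$duration) * cf$fs))
    idx <- seq.int(s0 + 1L, s1) # 1-based slice of the 0-based [s0, s1)
    hold <- if (ev$type == "post_inhalation") -0.5 else 0.5
    resp[idx] <- hold + cf$apnea_residual * (resp_norm[idx] - hold)
    ev_samples <- rbind(ev_samples,
                        data.frame(start_sample = s0, end_sample = s1,
                                   type = ev$type, stringsAsFactors = FALSE))
  }
  clean_resp <- cf$breath_amp * resp

  ## breath troughs: phase wraps at each cycle start (0-based samples)
  k <- seq.int(0, floor(cf$duration * cf$breath_rate_hz))
  troughs <- round(k / cf$breath_rate_hz * cf$fs)
  troughs <- troughs[troughs < n]

  ## BCG pulse train
  mean_ibi <- 60 / cf$hr_bpm
  n_beats <- ceiling(cf$duration / mean_ibi) + 2L
  ibis <- mean_ibi + rng$rnorm(n_beats, 0, cf$hr_jitter)
  ibis <- pmax(ibis, 0.3)
  beat_starts <- cumsum(c(0, ibis))
  beat_starts <- beat_starts[beat_starts < cf$duration]
  # the wave complex has a roughly fixed physiological duration; it does not
  # stretch with slow heart rates (the extra time is quiet diastole)
  beat_dur <- min(max(0.7 * mean_ibi, 0.3), 0.65)
  pk <- .bcg_wave_peak()
  clean_bcg <- numeric(n)
  j_peaks <- integer(0)
  # beats are laid down in continuous time (fractional sample offsets): the
  # sampled pulse train then has no subharmonic leakage from grid rounding
  for (b in beat_starts) {
    i0 <- max(1L, floor(b * cf$fs) + 1L)
    i1 <- min(n, ceiling((b + beat_dur) * cf$fs) + 1L)
    if (i1 < i0) next
    tt <- ((i0:i1) - 1) / cf$fs
    ph <- (tt - b) / beat_dur
    inb <- ph >= 0 & ph < 1
    clean_bcg[(i0:i1)[inb]] <- clean_bcg[(i0:i1)[inb]] +
      cf$bcg_amp * .bcg_wave(ph[inb]) / pk$value
    jp <- round((b + pk$phase * beat_dur) * cf$fs)
    if (jp >= 0 && jp < n) j_peaks <- c(j_peaks, jp)
  }
  j_peaks <- sort(unique(j_peaks))

  ## motion artifacts: exponentially decaying random transients
  motion <- numeric(n)
  for (mv in cf$motion_events) {
    mv <- as.numeric(mv)
    s0 <- floor(mv[1] * cf$fs)
    len <- max(1L, round(mv[2] * cf$fs))
    idx <- seq.int(s0 + 1L, min(n, s0 + len))
    tau <- mv[2] / 3
    shape <- exp(-(seq_along(idx) - 1) / (tau * cf$fs))
    motion[idx] <- motion[idx] + mv[3] * shape * rng$rnorm(length(idx), 0, 1)
  }

  ## noise
  clean <- clean_resp + clean_bcg
  noise_sd <- cf$noise_sd
  if (!is.null(cf$snr_db)) {
    rms <- sqrt(mean((clean - mean(clean))^2))
    noise_sd <- rms / 10^(cf$snr_db / 20)
  }
  noise <- if (noise_sd > 0) rng$rnorm(n, 0, noise_sd) else numeric(n)

  samples <- cf$dc_offset + clean + motion + noise

  ## frame labels from the nominal trough schedule
  frames <- if (length(troughs) >= 2) {
    data.frame(start_sample = troughs[-length(troughs)],
               end_sample = troughs[-1])
  } else {
    data.frame(start_sample = integer(0), end_sample = integer(0))
  }
  frames$label <- vapply(seq_len(nrow(frames)), function(i) {
    fr <- frames[i, ]
    ov <- 0
    if (nrow(ev_samples)) {
      ov <- max(pmin(fr$end_sample, ev_samples$end_sample) -
                pmax(fr$start_sample, ev_samples$start_sample), 0)
    }
    if (ov > 0.5 * (fr$end_sample - fr$start_sample)) "apnea" else "normal"
  }, character(1))

  truth <- structure(
    list(j_peak_samples = j_peaks, breath_trough_samples = troughs,
         frames = frames, apnea_events = ev_samples,
         clean_respiration = clean_resp, clean_bcg = clean_bcg,
         noise = noise, motion = motion, dc_offset = cf$dc_offset,
         noise_sd = noise_sd),
    class = "ground_truth")

  rec <- raw_record(samples, cf$fs,
                    meta = list(source = "bcgsleep::synthesize",
                                seed = cf$seed))
  list(record = rec, truth = truth)
}

# Private RNG stream: seeds a local Mersenne-Twister without disturbing the
# caller's .Random.seed.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  list(
    rnorm = function(...) stats::rnorm(...),
    runif = function(...) stats::runif(...),
    restore = function() {
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
}

#' Write and read ground-truth annotations
#'
#' Annotations are stored as CSV with columns
#' `kind,start_sample,end_sample,label`: one `jpeak` row per J-peak
#' (start = end = sample), one `trough` row per breath trough, one `frame`
#' row per breath frame (label `normal`/`apnea`) and one `apnea` row per
#' injected event. Sample indices are 0-based, intervals half-open.
#'
#' @param truth A `ground_truth` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(truth, path) {
  rows <- data.frame(kind = character(0), start_sample = integer(0),
                     end_sample = integer(0), label = character(0),
                     stringsAsFactors = FALSE)
  if (length(truth$j_peak_samples)) {
    rows <- rbind(rows, data.frame(kind = "jpeak",
                                   start_sample = truth$j_peak_samples,
                                   end_sample = truth$j_peak_samples,
                                   label = ""))
  }
  if (length(truth$breath_trough_samples)) {
    rows <- rbind(rows, data.frame(kind = "trough",
                                   start_sample = truth$breath_trough_samples,
                                   end_sample = truth$breath_trough_samples,
                                   label = ""))
  }
  if (nrow(truth$frames)) {
    rows <- rbind(rows, data.frame(kind = "frame",
                                   start_sample = truth$frames$start_sample,
                                   end_sample = truth$frames$end_sample,
                                   label = truth$frames$label))
  }
  if (nrow(truth$apnea_events)) {
    rows <- rbind(rows, data.frame(kind = "apnea",
                                   start_sample = truth$apnea_events$start_sample,
                                   end_sample = truth$apnea_events$end_sample,
                                   label = truth$apnea_events$type))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(kind = "character",
                                       start_sample = "integer",
                                       end_sample = "integer",
                                       label = "character"))
  if (nrow(df) == 0) {
    df$label <- character(0)
  }
  df$label[is.na(df$label)] <- ""
  df
}
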
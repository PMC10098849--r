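# Shared fixtures: all synthetic, generated at test time.

# Standard clean recording (no noise) at the nominal operating point.
clean_sim <- function(duration = 60, rate = 0.3, hr = 70, jitter = 0.02,
                      seed = 7, ...) {
  synthesize(synth_config(duration = duration, breath_rate_hz = rate,
                          hr_bpm = hr, hr_jitter = jitter, seed = seed, ...))
}

# Noisy recording at a given SNR.
noisy_sim <- function(duration = 60, rate = 0.3, hr = 70, snr_db = 10,
                      seed = 7, ...) {
  synthesize(synth_config(duration = duration, breath_rate_hz = rate,
                          hr_bpm = hr, snr_db = snr_db, seed = seed, ...))
}

# Fraction of reference events matched by a detection within tol samples.
match_rate <- function(detected, reference, tol) {
  if (!length(reference)) return(NA_real_)
  if (!length(detected)) return(0)
  mean(vapply(reference, function(p) min(abs(detected - p)) <= tol,
              logical(1)))
}

# O(n^2) double-loop cross-correlation oracle (scalar accumulation only).
xcorr_oracle <- function(f, g) {
  nf <- length(f); ng <- length(g)
  lags <- seq.int(-(ng - 1L), nf - 1L)
  val <- numeric(length(lags))
  for (i in seq_along(lags)) {
    n <- lags[i]
    acc <- 0
    for (k in seq_len(nf)) {
      j <- k + n
      if (j >= 1 && j <= ng) acc <- acc + f[k] * g[j]
    }
    val[i] <- acc
  }
  list(lag = lags, value = val)
}

# Feature names used for classifier fixtures.
.feat_names <- c("avnn_s", "sdnn_s", "cv", "ti_s", "n_beats", "similarity_pct")

# Run the pipeline on one synthetic subject and return labelled features.
subject_features <- function(seed, rate, apnea = list(), duration = 180,
                             hr = 70, snr_db = 10) {
  sim <- synthesize(synth_config(duration = duration, breath_rate_hz = rate,
                                 hr_bpm = hr, snr_db = snr_db, seed = seed,
                                 apnea_events = apnea))
  res <- run_pipeline(sim$record)
  ft <- res$features
  ft$y <- label_frames(ft, sim$truth)
  list(features = ft, truth = sim$truth)
}
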
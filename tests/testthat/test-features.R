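# Breath-frame segmentation and per-frame features.

test_that("clean respiration segments into one frame per breath cycle", {
  ph <- ((0:2999) / 50 * 0.3) %% 1
  resp <- bcgsleep:::.breath_cycle(ph, 0.4)
  fr <- segment_breath_frames(resp, 50)
  expect_gte(nrow(fr), 17)
  expect_lte(nrow(fr), 18)
  expect_true(all(!fr$flagged))
  durations <- (fr$end_sample - fr$start_sample) / 50
  expect_true(all(abs(durations - 1 / 0.3) < 0.2))
  # frames tile without overlap
  expect_true(all(fr$start_sample[-1] == fr$end_sample[-nrow(fr)]))
})

test_that("frame boundaries land on ground-truth troughs (clean data)", {
  # D5 carries the breath harmonics; including it keeps the valley shape
  sim <- clean_sim(duration = 60, rate = 0.3, seed = 2)
  sep <- separate(sim$record, include_d5_resp = TRUE)
  fr <- segment_breath_frames(sep$respiration, 50)
  bounds <- sort(unique(c(fr$start_sample, fr$end_sample)))
  gt <- sim$truth$breath_trough_samples
  interior <- gt[gt > 100 & gt < 2900]
  devs <- vapply(interior, function(p) min(abs(bounds - p)), numeric(1))
  expect_lte(max(devs), 3)
})

test_that("degenerate channels fall back to flagged fixed-length frames", {
  fr <- segment_breath_frames(numeric(1000), 50)
  expect_true(all(fr$flagged))
  expect_true(all(fr$end_sample - fr$start_sample == 250))
  fr2 <- segment_breath_frames(rnorm(1000, sd = 1e-12) + 5, 50)
  expect_true(nrow(fr2) > 0)
})

test_that("over-long frames are split to the admissible period range", {
  # 40 s of silence between two breaths
  t <- (0:2999) / 50
  x <- ifelse(t < 5, sin(2 * pi * 0.3 * t),
              ifelse(t > 55, sin(2 * pi * 0.3 * t), 0))
  fr <- segment_breath_frames(x, 50)
  durations <- (fr$end_sample - fr$start_sample) / 50
  expect_true(all(durations <= 15 + 1e-9))
  expect_true(all(durations >= 1 - 1e-9))
  expect_true(any(fr$flagged))
})

test_that("avnn and sdnn reproduce closed-form examples and an oracle", {
  expect_equal(avnn(c(0, 50, 100), 50), 1.0)
  expect_equal(avnn(c(0, 40, 100), 50), 1.0)
  expect_equal(sdnn(c(0, 50, 100), 50), 0)
  expect_equal(sdnn(c(0, 40, 100), 50), sqrt(((0.8 - 1)^2 + (1.2 - 1)^2) / 1))
  expect_equal(round(sdnn(c(0, 40, 100), 50), 4), 0.2828)
  expect_true(is.na(avnn(c(10), 50)))
  expect_true(is.na(sdnn(integer(0), 50)))
  set.seed(31)
  for (i in 1:5) {
    pk <- sort(sample(0:2000, 12))
    ivl <- diff(pk) / 50
    expect_equal(avnn(pk, 50), sum(ivl) / length(ivl))
    expect_equal(sdnn(pk, 50),
                 sqrt(sum((ivl - mean(ivl))^2) / (length(ivl) - 1)))
  }
})

test_that("cv follows the text reading with the printed form as option", {
  expect_equal(cv_nn(1.0, 0.2828), 0.2828)
  expect_equal(cv_nn(1.0, 0), 0)
  expect_equal(cv_nn(1.0, 0.2828, reciprocal = TRUE), 1 / 0.2828)
  expect_equal(cv_nn(2, 0.4), cv_nn(3 * 2, 3 * 0.4)) # scale invariance
  expect_true(is.na(cv_nn(NA_real_, 0.1)))
})

test_that("breath period is frame length over sampling rate and tiles", {
  expect_equal(breath_period(0, 167, 50), 3.34)
  fr <- segment_breath_frames(bcgsleep:::.breath_cycle(
    ((0:2999) / 50 * 0.3) %% 1, 0.4), 50)
  periods <- breath_period(fr$start_sample, fr$end_sample, 50)
  expect_equal(sum(periods),
               (max(fr$end_sample) - min(fr$start_sample)) / 50)
})

test_that("cross-correlation equals the double-loop oracle exactly", {
  expect_equal(cross_correlation(c(1, 0), c(1, 0))$value[2], 1)
  r <- cross_correlation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(max(r$value), 14)
  expect_equal(r$lag[which.max(r$value)], 0)
  set.seed(41)
  for (i in 1:5) {
    f <- sample(-9:9, sample(3:12, 1), replace = TRUE)
    g <- sample(-9:9, sample(3:12, 1), replace = TRUE)
    expect_identical(cross_correlation(f, g)$value, xcorr_oracle(f, g)$value)
    # symmetry R_fg(n) = R_gf(-n)
    a <- cross_correlation(f, g)
    b <- cross_correlation(g, f)
    expect_equal(a$value, rev(b$value))
  }
  expect_error(cross_correlation(numeric(0), 1), "empty")
})

test_that("similarity is 100 for the template itself and scale-invariant", {
  tm <- standard_template(80)
  expect_equal(similarity(as.numeric(tm), tm), 100)
  expect_equal(similarity(3 * as.numeric(tm), tm), 100)
  expect_equal(similarity(as.numeric(tm) + 2.5, tm), 100) # offset too
  expect_equal(similarity(numeric(50), tm), 0)
  expect_error(similarity(c(1, 2), tm), "short")
})

test_that("similarity is bounded and robust to modest time shifts", {
  set.seed(51)
  tm <- standard_template(64)
  for (i in 1:20) {
    x <- rnorm(sample(20:200, 1))
    xi <- similarity(x, tm)
    expect_gte(xi, 0)
    expect_lte(xi, 100 + 1e-9)
  }
  # segmentation-phase robustness: a frame cut k samples late is a circular
  # shift of the cycle; small shifts barely move xi and even a 10% shift
  # keeps a normal breath far above the apnea band
  base <- as.numeric(standard_template(200))
  xi0 <- similarity(base, tm)
  for (k in c(2, 4)) {
    shifted <- c(base[-seq_len(k)], base[seq_len(k)])
    expect_lt(abs(similarity(shifted, tm) - xi0), 2)
  }
  shifted10 <- c(base[-seq_len(20)], base[seq_len(20)])
  expect_gt(similarity(shifted10, tm), 70)
})

test_that("near-flat apnea frames score below 40", {
  set.seed(61)
  tm <- standard_template(64)
  vals <- vapply(1:30, function(i) {
    frame <- 0.05 * as.numeric(standard_template(167)) + rnorm(167, 0, 0.02)
    similarity(frame, tm)
  }, numeric(1))
  expect_lt(mean(vals), 40)
})

test_that("feature extraction marks undefined features but keeps Ti and xi", {
  tm <- standard_template(64)
  wave <- as.numeric(standard_template(150))
  fv <- extract_features(wave, peaks = c(40), 0, 150, 50, template = tm)
  expect_true(is.na(fv$avnn_s) && is.na(fv$sdnn_s) && is.na(fv$cv))
  expect_equal(fv$ti_s, 3)
  expect_equal(fv$n_beats, 1)
  expect_gt(fv$similarity_pct, 99)
  expect_named(fv, c("frame_start", "frame_end", "avnn_s", "sdnn_s", "cv",
                     "ti_s", "n_beats", "similarity_pct"))
})

test_that("frame HRV features agree with ground-truth beat times", {
  sim <- clean_sim(duration = 60, seed = 6)
  sep <- separate(sim$record)
  jp <- detect_jpeaks(sep$bcg, 50)
  ft <- feature_table(sep, jp)
  gt_peaks <- sim$truth$j_peak_samples
  for (i in which(ft$n_beats >= 3)) {
    gt_in <- gt_peaks[gt_peaks >= ft$frame_start[i] &
                        gt_peaks < ft$frame_end[i]]
    if (length(gt_in) >= 2) {
      expect_lt(abs(ft$avnn_s[i] - avnn(gt_in, 50)), 1 / 50)
      expect_lt(abs(ft$sdnn_s[i] - sdnn(gt_in, 50)), 1 / 50)
    }
  }
})

test_that("normal frames score high and apnea frames low on average", {
  sim <- noisy_sim(duration = 120, seed = 17,
                   apnea_events = list(list(40, 35, "post_inhalation")))
  res <- run_pipeline(sim$record)
  ft <- res$features
  y <- label_frames(ft, sim$truth)
  expect_gt(mean(ft$similarity_pct[y == 0]), 70)
  expect_lt(mean(ft$similarity_pct[y == 1]), 40)
})
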
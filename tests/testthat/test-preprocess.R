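test_that("band-pass filter rejects DC, keeps 10 Hz, attenuates 60 Hz", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  x10 <- bandpass_filter(ecg_record("a", fs, sin(2 * pi * 10 * t)))
  expect_gt(max(abs(x10$samples[mid])), 0.95)
  expect_lt(max(abs(x10$samples[mid])), 1.05)
  x60 <- bandpass_filter(ecg_record("b", fs, sin(2 * pi * 60 * t)))
  expect_lt(max(abs(x60$samples[mid])), 0.2)
  xc <- bandpass_filter(ecg_record("c", fs, rep(3.5, 5000)))
  expect_lt(max(abs(xc$samples)), 1e-6 * 3.5)
  expect_length(x10$samples, length(t))
  expect_error(bandpass_filter(ecg_record("d", 80, rnorm(100))), "80 Hz")
})

test_that("quality screen flags flatline, NaN and broadband noise, passes clean ECG", {
  s <- quick_subject(seed = 11, ecg_noise = 0.01)
  ecg <- gen_ecg(s$rr, s$cfg, s$truth)
  qs <- quality_screen(ecg)
  expect_true(all(qs$pass))
  # inject 2 s of constant samples
  bad <- ecg
  bad$samples[1000:1500] <- bad$samples[1000]
  qs2 <- quality_screen(bad)
  expect_false(qs2$pass[1])
  expect_equal(qs2$reason[1], "flatline")
  # all-NaN window
  bad2 <- ecg
  bad2$samples[30001:60000] <- NaN
  expect_equal(quality_screen(bad2)$reason[2], "nonfinite")
  # very large noise flags the record
  noisy <- s$cfg; noisy$ecg_noise_sd <- 1.5
  ecgn <- gen_ecg(s$rr, noisy, s$truth)
  expect_true(any(!quality_screen(ecgn)$pass))
  expect_error(quality_screen(ecg_record("e", 250, numeric(0))), "empty")
})

test_that("Pan-Tompkins recovers nearly all beats on clean synthetic ECG", {
  s <- quick_subject(seed = 21, session = 70, ecg_noise = 0)
  s$cfg$ingestion_time <- 5
  ecg <- bandpass_filter(gen_ecg(s$rr, s$cfg, s$truth))
  pk <- detect_r_peaks(ecg)
  truth_idx <- round(s$rr$r_times * 250) + 1
  truth_idx <- truth_idx[truth_idx > 80 & truth_idx < length(ecg$samples) - 120]
  hit <- vapply(truth_idx, function(ti) any(abs(pk$indices - ti) <= 2), logical(1))
  expect_gte(mean(hit), 0.99)
  # override replaces detection exactly
  ov <- c(100L, 400L, 900L)
  expect_identical(detect_r_peaks(ecg, peaks_override = ov)$indices, ov)
  expect_error(detect_r_peaks(ecg_record("x", 250, rnorm(100))), "short")
})

test_that("CGM delay correction shifts once and only once", {
  g <- glucose_series(c(15, 60), c(100, 150))
  gc <- correct_cgm_delay(g)
  expect_equal(gc$t_min, c(0, 45))
  expect_true(gc$delay_corrected)
  expect_error(correct_cgm_delay(gc), "already")
  ge <- correct_cgm_delay(glucose_series(numeric(0), numeric(0)))
  expect_length(ge$t_min, 0)
})

test_that("segmentation yields the expected window counts and drops sparse windows", {
  fs <- 250
  dur <- 180 * 60
  ecg <- ecg_record("seg", fs, numeric(dur * fs))
  peaks <- rpeak_series(seq(1, dur * fs, by = round(0.8 * fs)), fs)
  w120 <- segment_windows(ecg, peaks, stride_s = 120)
  expect_length(w120, 90)
  w60 <- segment_windows(ecg, peaks, stride_s = 60)
  expect_length(w60, 179)
  # all windows carry ~150 beats; a sparse record drops everything
  sparse <- rpeak_series(seq(1, dur * fs, by = 10 * fs), fs)  # 10-s beats
  expect_length(segment_windows(ecg, sparse, stride_s = 120), 0)
  # record shorter than a window: empty list
  expect_length(segment_windows(ecg_record("s2", fs, numeric(100 * fs)), peaks), 0)
  # window membership by the later beat of each pair
  expect_true(all(w120[[1]]$beat_times < 120))
})

test_that("beat extraction follows the 80-pre / 120-post geometry exactly", {
  ecg <- ecg_record("beats", 250, as.numeric(0:4999))
  # R at 0-based sample 1000 -> 0-based samples 920..1119
  m <- extract_beats(ecg, 1001L)
  expect_equal(dim(m), c(1L, 200L))
  expect_equal(m[1, ], as.numeric(920:1119))
  # insufficient pre-samples: dropped, never padded
  expect_equal(nrow(extract_beats(ecg, 51L)), 0L)
  # k peaks give at most k rows
  expect_lte(nrow(extract_beats(ecg, c(51L, 1001L, 2001L, 4990L))), 4L)
})

test_that("beat-count fixing trims to the dataset minimum preserving order", {
  w <- fake_windows(6)
  counts <- vapply(w, function(x) nrow(x$beats), integer(1))
  fixed <- fix_beat_count(w)
  n_min <- min(counts)
  expect_equal(attr(fixed, "n_min"), n_min)
  for (i in seq_along(w)) {
    expect_equal(fixed[[i]]$beats, w[[i]]$beats[seq_len(n_min), , drop = FALSE])
  }
  # equal counts: unchanged
  eq <- lapply(w, function(x) { x$beats <- x$beats[1:15, ]; x })
  expect_equal(attr(fix_beat_count(eq), "n_min"), 15L)
})

test_that("labeling uses the nearest delay-corrected sample, >= 180 threshold", {
  w <- list(list(subject_id = "s", window_start = 0),    # center 1 min
            list(subject_id = "s", window_start = 660))  # center 12.5 min
  g <- glucose_series(c(0, 10, 15), c(180, 179, 185), delay_corrected = TRUE)
  lw <- label_windows(w, g)
  expect_equal(lw[[1]]$label, "hyperglycemia")   # glucose exactly 180
  # center 12.5 equidistant from 10 and 15 -> earlier sample wins (179)
  expect_equal(lw[[2]]$glucose, 179)
  expect_equal(lw[[2]]$label, "euglycemia")
  # uncorrected series refused
  expect_error(label_windows(w, glucose_series(0, 100)), "delay-corrected")
  # window too far from any sample: dropped and logged
  far <- list(list(subject_id = "s", window_start = 3600))
  lw2 <- label_windows(far, g)
  expect_length(lw2, 0)
  expect_equal(attr(lw2, "drop_log")$reason, "no_cgm_match")
})

test_that("pipeline conservation: every window is labeled or logged", {
  s <- quick_subject(seed = 31)
  w <- preprocess_subject(gen_ecg(s$rr, s$cfg, s$truth), s$cgm)
  n_windows <- floor((s$cfg$session_minutes * 60 - 120) / 120) + 1
  expect_equal(length(w) + nrow(attr(w, "drop_log")), n_windows)
  # labels against the ground truth: fraction of hyperglycemia windows
  # matches the fraction of truth time above threshold within one CGM sample
  frac_true <- mean(s$truth$values >= 180)
  frac_lab <- mean(vapply(w, `[[`, character(1), "label") == "hyperglycemia")
  expect_lt(abs(frac_true - frac_lab), 0.12)
  # every labeled window carries a full beat matrix
  expect_true(all(vapply(w, function(x) ncol(x$beats) == 200L, logical(1))))
})
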
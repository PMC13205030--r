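test_that("glucose profile is gamma-shaped with exact peak and baseline limits", {
  cfg <- subject_config(baseline_glucose = 90, excursion_amplitude = 100,
                        excursion_timescale = 45, ingestion_time = 30)
  g <- gen_glucose_profile(cfg)
  expect_equal(max(g$values), 190)
  expect_equal(g$times[which.max(g$values)], 75)
  expect_true(all(g$values[g$times < 30] == 90))
  # zero amplitude: constant at baseline
  g0 <- gen_glucose_profile(subject_config(excursion_amplitude = 0))
  expect_true(all(g0$values == 90))
  # sub-threshold amplitude never reaches 180
  g80 <- gen_glucose_profile(subject_config(excursion_amplitude = 80))
  expect_lt(max(g80$values), 180)
  expect_error(gen_glucose_profile(subject_config(excursion_timescale = -1)),
               "positive")
})

test_that("RR series couples to glucose with the configured sign and strength", {
  # decoupled: session mean NN within 2 SE of the configured baseline
  cfg0 <- subject_config(coupling_strength = 0, seed = 4, rr_noise_sd = 15)
  rr0 <- gen_rr_series(gen_glucose_profile(cfg0), cfg0)
  se <- sd(rr0$nn_ms) / sqrt(length(rr0$nn_ms))
  expect_lt(abs(mean(rr0$nn_ms) - 900), 2 * se + 2)
  # strong coupling: NN shorter during the glucose peak than when fasting
  cfg1 <- subject_config(coupling_strength = 1, excursion_amplitude = 120, seed = 5)
  rr1 <- gen_rr_series(gen_glucose_profile(cfg1), cfg1)
  peak_w <- rr1$beat_times / 60 >= 60 & rr1$beat_times / 60 <= 90
  base_w <- rr1$beat_times / 60 <= 25
  expect_lt(mean(rr1$nn_ms[peak_w]), mean(rr1$nn_ms[base_w]))
  # degenerate: no noise, no modulation, no coupling -> constant NN
  cfgc <- subject_config(coupling_strength = 0, rr_noise_sd = 0,
                         lf_amp_ms = 0, hf_amp_ms = 0)
  rrc <- gen_rr_series(gen_glucose_profile(cfgc), cfgc)
  expect_lt(diff(range(rrc$nn_ms)), 1e-9)
  # all intervals clamped into the physiologic band
  expect_true(all(rr1$nn_ms >= 300 & rr1$nn_ms <= 2000))
})

test_that("rendered ECG has R as beat extremum and reproducible templates", {
  # constant NN of 900 ms (225 samples at 250 Hz) keeps every R on the
  # sample grid, so rendered templates are exactly identical
  cfg <- subject_config(seed = 7, session_minutes = 90, ingestion_time = 5,
                        ecg_noise_sd = 0, coupling_strength = 0,
                        pr_shift_ms = 0, qt_shift_ms = 0, rr_noise_sd = 0,
                        lf_amp_ms = 0, hf_amp_ms = 0)
  truth <- gen_glucose_profile(cfg)
  rr <- gen_rr_series(truth, cfg)
  ecg <- gen_ecg(rr, cfg, truth)
  idx <- round(rr$r_times * 250) + 1
  idx <- idx[idx > 80 & idx + 120 <= length(ecg$samples)]
  beats <- extract_beats(ecg, idx)
  # glucose factor 0, noise 0: every beat identical up to placement
  ref <- beats[5, ]
  expect_true(all(apply(beats, 1, function(b) max(abs(b - ref))) < 1e-6))
  # R deflection is the extremum of each beat
  expect_true(all(apply(beats, 1, which.max) == 81))
})

test_that("CGM model applies a pure 15-min delay on the 5-min grid", {
  cfg <- subject_config(cgm_noise_sd = 0, session_minutes = 180)
  truth <- gen_glucose_profile(cfg)
  cgm <- gen_cgm(truth, cfg)
  # 180-min session: 34 samples on the 15..180 grid
  expect_identical(cgm$t_min, seq(15, 180, by = 5))
  expect_length(cgm$values, 34)
  tf <- approxfun(truth$times, truth$values)
  expect_equal(cgm$values, tf(cgm$t_min - 15), tolerance = 1e-12)
  expect_false(cgm$delay_corrected)
  # constant truth stays constant
  cfg0 <- subject_config(excursion_amplitude = 0, cgm_noise_sd = 0)
  cgm0 <- gen_cgm(gen_glucose_profile(cfg0), cfg0)
  expect_true(all(cgm0$values == 90))
})

test_that("cohort generation is deterministic and honours its config", {
  cc <- cohort_config(n_subjects = 4, fraction_crossing_threshold = 0,
                      lag_distribution = data.frame(lag_steps = 0L, prob = 1),
                      master_seed = 3)
  coh <- gen_cohort(cc, render_ecg = FALSE)
  # no subject's truth exceeds 180
  expect_true(all(vapply(coh, function(s) max(s$truth$values) < 180, logical(1))))
  expect_true(all(vapply(coh, function(s) s$cfg$lag_steps == 0L, logical(1))))
  # byte-identical regeneration on disk
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  cc2 <- cohort_config(n_subjects = 2, master_seed = 9, session_minutes = 90)
  gen_cohort(cc2, out_dir = d1)
  gen_cohort(cc2, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 8)   # wfdb pair, csvs, truth json per subject
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  # refuses to clobber an existing non-empty directory
  expect_error(gen_cohort(cc2, out_dir = d1), "overwrite")
})

test_that("WFDB round trip preserves the waveform to ADC resolution", {
  set.seed(2)
  ecg <- ecg_record("rt", 250, rnorm(5000, sd = 0.3))
  d <- file.path(tempdir(), "wfdb_rt")
  write_wfdb(ecg, d)
  back <- read_wfdb(file.path(d, "rt"))
  expect_equal(back$fs, 250)
  expect_lt(max(abs(back$samples - ecg$samples)), 5.1e-4)  # ADC half-step
})
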
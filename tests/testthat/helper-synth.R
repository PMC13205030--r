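# Shared small fixtures, built in code at test time.

# a seeded random RR window (~2 min of beats around 800 ms)
random_rr_window <- function(seed, n = 140, mean_ms = 850, sd_ms = 40) {
  set.seed(seed)
  nn <- pmax(400, rnorm(n, mean_ms, sd_ms))
  bt <- cumsum(nn) / 1000
  list(nn = nn, bt = bt)
}

# synthetic labeled windows with shared beat geometry for dataset-level tests
fake_windows <- function(n = 12, n_beats = 20, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nn <- rnorm(n_beats + 10, 800, 30)
    list(subject_id = sprintf("S%02d", (i - 1) %/% 6 + 1),
         window_start = ((i - 1) %% 6) * 120,
         nn_ms = nn,
         beat_times = cumsum(nn) / 1000,
         beats = matrix(rnorm((n_beats + (i %% 3)) * 200, sd = 0.2),
                        ncol = 200),
         glucose = 100 + 90 * (i %% 2),
         label = if (i %% 2 == 1) "euglycemia" else "hyperglycemia")
  })
}

# a quick small subject for pipeline-level tests (short session)
quick_subject <- function(seed = 1, session = 90, lag = 0L, coupling = 0.9,
                          ecg_noise = 0.01) {
  cfg <- subject_config(subject_id = paste0("T", seed), seed = seed,
                        session_minutes = session, lag_steps = lag,
                        ingestion_time = min(30, session - 60),
                        coupling_strength = coupling, ecg_noise_sd = ecg_noise)
  truth <- gen_glucose_profile(cfg)
  rr <- gen_rr_series(truth, cfg)
  list(cfg = cfg, truth = truth, rr = rr, cgm = gen_cgm(truth, cfg))
}
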
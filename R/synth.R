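#' Subject configuration for the synthetic OGTT session
#'
#' Describes one synthetic subject: a fasting baseline, a gamma-shaped oral
#' glucose tolerance test (OGTT) excursion, and the coupling between glucose
#' and RR-interval dynamics. `lag_steps` is in 5-min units; a positive value
#' means the glucose excursion trails the HRV change (the heart responds
#' before glucose is seen at the sensor under this package's sign convention).
#'
#' @param subject_id character id.
#' @param baseline_glucose fasting glucose, mg/dL.
#' @param excursion_amplitude peak excursion above baseline, mg/dL.
#' @param excursion_timescale time-to-peak of the excursion, minutes.
#' @param ingestion_time glucose ingestion time, minutes from session start.
#' @param lag_steps HRV-glucose lag in 5-min steps (positive: glucose trails HRV).
#' @param coupling_strength dimensionless coupling in `[0, 1]`.
#' @param baseline_mean_rr fasting mean RR interval, ms.
#' @param rr_noise_sd beat-to-beat white jitter sd, ms.
#' @param ecg_noise_sd additive ECG noise sd, mV.
#' @param seed integer RNG seed for this subject.
#' @param session_minutes session length, minutes.
#' @param cgm_noise_sd CGM measurement noise sd, mg/dL.
#' @param lf_amp_ms,hf_amp_ms baseline amplitudes of the 0.1 Hz and 0.25 Hz
#'   RR modulations, ms.
#' @param pr_shift_ms,qt_shift_ms PR/QT prolongation at peak normalized
#'   glucose, ms (the mild conduction effect rendered into beat morphology).
#' @return a `subject_config`.
#' @export
subject_config <- function(subject_id = "S01",
                           baseline_glucose = 90,
                           excursion_amplitude = 110,
                           excursion_timescale = 45,
                           ingestion_time = 30,
                           lag_steps = 0L,
                           coupling_strength = 0.8,
                           baseline_mean_rr = 900,
                           rr_noise_sd = 10,
                           ecg_noise_sd = 0.01,
                           seed = 1L,
                           session_minutes = 180,
                           cgm_noise_sd = 3,
                           lf_amp_ms = 40,
                           hf_amp_ms = 25,
                           pr_shift_ms = 10,
                           qt_shift_ms = 15) {
  stopifnot_scalar(baseline_glucose, "baseline_glucose")
  stopifnot_scalar(excursion_amplitude, "excursion_amplitude")
  stopifnot_scalar(coupling_strength, "coupling_strength")
  stopifnot_scalar(baseline_mean_rr, "baseline_mean_rr")
  if (baseline_glucose <= 0) stop("baseline_glucose must be > 0")
  if (excursion_amplitude < 0) stop("excursion_amplitude must be >= 0")
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must be in [0, 1]")
  }
  if (baseline_mean_rr < 400 || baseline_mean_rr > 1500) {
    stop("baseline_mean_rr must be in [400, 1500] ms")
  }
  cfg <- list(
    subject_id = as.character(subject_id),
    baseline_glucose = baseline_glucose,
    excursion_amplitude = excursion_amplitude,
    excursion_timescale = excursion_timescale,
    ingestion_time = ingestion_time,
    lag_steps = as.integer(lag_steps),
    coupling_strength = coupling_strength,
    baseline_mean_rr = baseline_mean_rr,
    rr_noise_sd = rr_noise_sd,
    ecg_noise_sd = ecg_noise_sd,
    seed = as.integer(seed),
    session_minutes = session_minutes,
    cgm_noise_sd = cgm_noise_sd,
    lf_amp_ms = lf_amp_ms,
    hf_amp_ms = hf_amp_ms,
    pr_shift_ms = pr_shift_ms,
    qt_shift_ms = qt_shift_ms
  )
  structure(cfg, class = "subject_config")
}

#' Ground-truth glucose profile for one OGTT session
#'
#' The excursion is gamma-shaped: for `u = (t - ingestion_time) / tau`,
#' `G(t) = baseline + A * u * exp(1 - u)` (peak exactly `baseline + A` at
#' `u = 1`), constant at baseline before ingestion, on a 1-min grid.
#'
#' @param cfg a [subject_config()].
#' @return a `glucose_truth` with fields `times` (min) and `values` (mg/dL).
#' @export
gen_glucose_profile <- function(cfg) {
  stopifnot(inherits(cfg, "subject_config"))
  if (cfg$excursion_timescale <= 0) stop("excursion_timescale must be positive")
  if (cfg$session_minutes < cfg$ingestion_time + 60) {
    stop("session must extend at least 60 min past ingestion")
  }
  times <- seq(0, cfg$session_minutes, by = 1)
  u <- pmax(0, (times - cfg$ingestion_time) / cfg$excursion_timescale)
  values <- cfg$baseline_glucose + cfg$excursion_amplitude * u * exp(1 - u)
  structure(list(times = times, values = values), class = "glucose_truth")
}

# min-max normalized glucose as a function of time (minutes), constant
# extrapolation beyond the session. Constant truth normalizes to 0.
normalized_glucose_fun <- function(truth) {
  rng <- range(truth$values)
  if (diff(rng) == 0) {
    function(t) rep(0, length(t))
  } else {
    g <- (truth$values - rng[1]) / diff(rng)
    stats::approxfun(truth$times, g, rule = 2)
  }
}

#' Glucose-coupled RR interval series
#'
#' Integrates an instantaneous RR process whose mean is
#' `baseline_mean_rr * (1 - 0.1 * c * g(t + lag))` and whose 0.1 Hz (LF) and
#' 0.25 Hz (HF) sinusoidal modulation amplitudes scale with
#' `(1 - c * g(t + lag))`, where `g` is the min-max normalized glucose truth,
#' `lag = lag_steps * 5` minutes and `c = coupling_strength`; white jitter of
#' sd `rr_noise_sd` is added per beat and NN intervals are clamped to
#' `[300, 2000]` ms. Positive lag means glucose trails the HRV change, so the
#' RR stream at time `t` reflects glucose at `t + lag`.
#'
#' @param truth a `glucose_truth` covering the session.
#' @param cfg the [subject_config()].
#' @return an `rr_series`: `r_times` (all beat times, s), `beat_times`
#'   (the later beat of each NN pair, s), `nn_ms`.
#' @export
gen_rr_series <- function(truth, cfg) {
  stopifnot(inherits(truth, "glucose_truth"), inherits(cfg, "subject_config"))
  if (max(truth$times) < cfg$session_minutes) {
    stop("glucose truth does not cover the session")
  }
  c0 <- cfg$coupling_strength
  if (cfg$baseline_mean_rr * (1 - 0.1 * c0) <= 0) {
    stop("coupling configuration makes mean RR non-positive")
  }
  gfun <- normalized_glucose_fun(truth)
  lag_min <- cfg$lag_steps * 5
  set.seed(derive_seed(cfg$seed, "rr"))
  dur <- cfg$session_minutes * 60
  # upper bound on beat count for preallocation
  nmax <- ceiling(dur / (0.3 * cfg$baseline_mean_rr / 1000)) + 2L
  beats <- numeric(nmax)
  t <- 0
  k <- 0L
  while (t < dur) {
    gl <- gfun(t / 60 + lag_min)
    m <- cfg$baseline_mean_rr * (1 - 0.1 * c0 * gl)
    amp <- 1 - c0 * gl
    rr <- m +
      amp * (cfg$lf_amp_ms * sin(2 * pi * 0.1 * t) +
               cfg$hf_amp_ms * sin(2 * pi * 0.25 * t)) +
      stats::rnorm(1, 0, cfg$rr_noise_sd)
    rr <- min(max(rr, 300), 2000)
    t <- t + rr / 1000
    k <- k + 1L
    beats[k] <- t
  }
  beats <- beats[seq_len(k)]
  rr_series(beats)
}

#' Construct an RR series from beat times
#' @param r_times strictly increasing beat (R-peak) times in seconds.
#' @return an `rr_series`.
#' @export
rr_series <- function(r_times) {
  stopifnot(length(r_times) >= 2, all(diff(r_times) > 0))
  structure(list(
    r_times = r_times,
    beat_times = r_times[-1],
    nn_ms = diff(r_times) * 1000
  ), class = "rr_series")
}

# Beat template: five Gaussian deflections (P, Q, R, S, T).
# Centers in ms relative to the R time; PR/QT modulation moves P earlier and
# T later with lagged normalized glucose.
BEAT_AMP <- c(P = 0.15, Q = -0.12, R = 1.0, S = -0.2, T = 0.3)
BEAT_SD <- c(P = 20, Q = 8, R = 10, S = 8, T = 45)

beat_centers <- function(gl, cfg) {
  c(-(150 + cfg$pr_shift_ms * gl), -25, 0, 25, 280 + cfg$qt_shift_ms * gl)
}

#' Render a synthetic single-lead ECG from an RR series
#'
#' Each beat is a sum of five Gaussian deflections (P, Q, R, S, T) placed
#' relative to its R time; the R deflection is the extremum of every beat.
#' PR and QT offsets increase linearly with the lagged normalized glucose by
#' `pr_shift_ms` / `qt_shift_ms` at peak. Gaussian noise of sd `ecg_noise_sd`
#' is added. Beats closer together than the template support are truncated at
#' the midpoint to the neighbouring beat (with a warning).
#'
#' @param rr an `rr_series`.
#' @param cfg the [subject_config()].
#' @param truth optional `glucose_truth`; when missing, morphology modulation
#'   is regenerated from `cfg`.
#' @param fs sampling rate, Hz.
#' @return an `ecg_record` (fields `subject_id`, `fs`, `samples` in mV, `t0`).
#' @export
gen_ecg <- function(rr, cfg, truth = gen_glucose_profile(cfg), fs = 250) {
  stopifnot(inherits(rr, "rr_series"))
  gfun <- normalized_glucose_fun(truth)
  lag_min <- cfg$lag_steps * 5
  dur <- cfg$session_minutes * 60
  n <- floor(dur * fs)
  x <- numeric(n)
  tpl_support <- c(-0.25, 0.45)  # seconds around R covered by the template
  rt <- rr$r_times
  rt <- rt[rt < dur]
  truncated <- 0L
  for (i in seq_along(rt)) {
    t_r <- rt[i]
    lo <- t_r + tpl_support[1]
    hi <- t_r + tpl_support[2]
    # truncate at midpoints when neighbouring beats overlap the support
    if (i > 1 && rt[i] - rt[i - 1] < diff(tpl_support)) {
      lo2 <- (rt[i] + rt[i - 1]) / 2
      if (lo2 > lo) { lo <- lo2; truncated <- truncated + 1L }
    }
    if (i < length(rt) && rt[i + 1] - rt[i] < diff(tpl_support)) {
      hi2 <- (rt[i] + rt[i + 1]) / 2
      if (hi2 < hi) { hi <- hi2; truncated <- truncated + 1L }
    }
    i0 <- max(1L, floor(lo * fs) + 1L)
    i1 <- min(n, ceiling(hi * fs))
    if (i1 < i0) next
    tt <- (((i0:i1) - 1) / fs - t_r) * 1000   # ms relative to R
    gl <- gfun(t_r / 60 + lag_min)
    ctr <- beat_centers(gl, cfg)
    seg <- numeric(length(tt))
    for (w in 1:5) {
      seg <- seg + BEAT_AMP[w] * exp(-0.5 * ((tt - ctr[w]) / BEAT_SD[w])^2)
    }
    x[i0:i1] <- x[i0:i1] + seg
  }
  if (truncated > 0) {
    warning(sprintf("%d beat renderings truncated (NN below template support)", truncated))
  }
  if (cfg$ecg_noise_sd > 0) {
    set.seed(derive_seed(cfg$seed, "ecg"))
    x <- x + stats::rnorm(n, 0, cfg$ecg_noise_sd)
  }
  ecg_record(cfg$subject_id, fs = fs, samples = x, t0 = 0)
}

#' Construct an ECG record
#' @param subject_id character id.
#' @param fs sampling rate in Hz.
#' @param samples signal in mV.
#' @param t0 start time in seconds.
#' @export
ecg_record <- function(subject_id, fs, samples, t0 = 0) {
  if (fs <= 0) stop("fs must be positive")
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 samples = as.numeric(samples), t0 = t0),
            class = "ecg_record")
}

#' Simulated CGM readout of a glucose truth
#'
#' Applies the sensor delay (truth shifted 15 min later), samples on the 5-min
#' grid starting at the first on-grid time at or after the delay, and adds iid
#' Gaussian measurement noise.
#'
#' @param truth a `glucose_truth`.
#' @param cfg the [subject_config()] (uses `cgm_noise_sd` and `seed`).
#' @param delay_min sensor delay, minutes.
#' @return a `glucose_series` with `delay_corrected = FALSE`.
#' @export
gen_cgm <- function(truth, cfg, delay_min = 15) {
  stopifnot(inherits(truth, "glucose_truth"))
  t_min <- seq(5 * ceiling(delay_min / 5), cfg$session_minutes, by = 5)
  tf <- stats::approxfun(truth$times, truth$values, rule = 2)
  vals <- tf(t_min - delay_min)
  if (cfg$cgm_noise_sd > 0) {
    set.seed(derive_seed(cfg$seed, "cgm"))
    vals <- vals + stats::rnorm(length(vals), 0, cfg$cgm_noise_sd)
  }
  glucose_series(t_min, vals, delay_corrected = FALSE)
}

#' Construct a glucose series
#' @param t_min timestamps in minutes (strictly increasing).
#' @param values glucose in mg/dL.
#' @param delay_corrected has the CGM sensor delay been removed?
#' @export
glucose_series <- function(t_min, values, delay_corrected = FALSE) {
  if (length(t_min) && any(diff(t_min) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(t_min = as.numeric(t_min), values = as.numeric(values),
                 delay_corrected = isTRUE(delay_corrected)),
            class = "glucose_series")
}
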
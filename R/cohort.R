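#' Cohort configuration for synthetic OGTT generation
#'
#' @param n_subjects number of subjects.
#' @param fraction_crossing_threshold fraction of subjects whose glucose truth
#'   crosses 180 mg/dL.
#' @param lag_distribution data.frame with columns `lag_steps` (integer, 5-min
#'   units) and `prob` (summing to 1); per-subject lags are drawn from it.
#' @param session_minutes session length.
#' @param master_seed master seed; per-subject seeds are derived from it.
#' @param coupling_strength,rr_noise_sd,ecg_noise_sd,cgm_noise_sd forwarded to
#'   every [subject_config()].
#' @param baseline_mean_rr fasting mean RR, ms (scalar, or length-2 range to
#'   draw per subject).
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          fraction_crossing_threshold = 0.5,
                          lag_distribution = data.frame(lag_steps = 0L, prob = 1),
                          session_minutes = 180,
                          master_seed = 1L,
                          coupling_strength = 0.8,
                          rr_noise_sd = 10,
                          ecg_noise_sd = 0.01,
                          cgm_noise_sd = 3,
                          baseline_mean_rr = c(820, 980)) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (fraction_crossing_threshold < 0 || fraction_crossing_threshold > 1) {
    stop("fraction_crossing_threshold must be in [0, 1]")
  }
  if (abs(sum(lag_distribution$prob) - 1) > 1e-8) {
    stop("lag_distribution probabilities must sum to 1")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    fraction_crossing_threshold = fraction_crossing_threshold,
    lag_distribution = lag_distribution,
    session_minutes = session_minutes,
    master_seed = as.integer(master_seed),
    coupling_strength = coupling_strength,
    rr_noise_sd = rr_noise_sd,
    ecg_noise_sd = ecg_noise_sd,
    cgm_noise_sd = cgm_noise_sd,
    baseline_mean_rr = baseline_mean_rr
  ), class = "cohort_config")
}

# Draw the per-subject configs for a cohort, deterministically from the
# master seed. Crossing subjects get excursion amplitudes that push the truth
# peak above 180 mg/dL; the rest stay strictly below.
cohort_subject_configs <- function(cc) {
  set.seed(derive_seed(cc$master_seed, "cohort"))
  n <- cc$n_subjects
  n_cross <- round(cc$fraction_crossing_threshold * n)
  crossing <- seq_len(n) %in% sample(n, n_cross)
  lag_idx <- sample(nrow(cc$lag_distribution), n, replace = TRUE,
                    prob = cc$lag_distribution$prob)
  mrr <- if (length(cc$baseline_mean_rr) == 2) {
    stats::runif(n, cc$baseline_mean_rr[1], cc$baseline_mean_rr[2])
  } else rep(cc$baseline_mean_rr, n)
  base <- stats::runif(n, 85, 100)
  # peak = base + A: crossers exceed 180 with margin, others stay below 175
  amp <- ifelse(crossing,
                (180 - base) + stats::runif(n, 15, 40),
                stats::runif(n, 40, 170 - base))
  tau <- stats::runif(n, 40, 55)
  lapply(seq_len(n), function(i) {
    subject_config(
      subject_id = sprintf("S%02d", i),
      baseline_glucose = base[i],
      excursion_amplitude = amp[i],
      excursion_timescale = tau[i],
      ingestion_time = 30,
      lag_steps = cc$lag_distribution$lag_steps[lag_idx[i]],
      coupling_strength = cc$coupling_strength,
      baseline_mean_rr = mrr[i],
      rr_noise_sd = cc$rr_noise_sd,
      ecg_noise_sd = cc$ecg_noise_sd,
      cgm_noise_sd = cc$cgm_noise_sd,
      seed = derive_seed(cc$master_seed, paste0("subject", i)),
      session_minutes = cc$session_minutes
    )
  })
}

#' Generate a synthetic OGTT cohort
#'
#' Produces, per subject, the ground-truth glucose profile, the CGM readout,
#' the RR series and (optionally) the rendered ECG. When `out_dir` is given,
#' each subject gets a directory with the ECG as a WFDB record plus a mirrored
#' CSV (`t_sec, mv`), the CGM as CSV (`t_min, glucose_mgdl`) and a
#' ground-truth JSON (configured lag, coupling, and the label timeline on the
#' truth grid). Identical configs reproduce identical outputs.
#'
#' @param cc a [cohort_config()].
#' @param out_dir optional output directory.
#' @param overwrite refuse to write into an existing `out_dir` unless TRUE.
#' @param render_ecg set FALSE to skip the (comparatively slow) waveform
#'   rendering when only RR/CGM-level analyses are needed.
#' @return invisibly, a list of per-subject lists
#'   (`cfg`, `truth`, `cgm`, `rr`, `ecg`, `files`).
#' @export
gen_cohort <- function(cc, out_dir = NULL, overwrite = FALSE, render_ecg = TRUE) {
  stopifnot(inherits(cc, "cohort_config"))
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
      stop("output directory exists and is non-empty; use overwrite = TRUE")
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  cfgs <- cohort_subject_configs(cc)
  lapply(cfgs, function(cfg) {
    truth <- gen_glucose_profile(cfg)
    cgm <- gen_cgm(truth, cfg)
    rr <- gen_rr_series(truth, cfg)
    ecg <- if (render_ecg) gen_ecg(rr, cfg, truth) else NULL
    files <- NULL
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, cfg$subject_id)
      dir.create(sdir, showWarnings = FALSE)
      utils::write.csv(
        data.frame(t_min = cgm$t_min, glucose_mgdl = cgm$values),
        file.path(sdir, "cgm.csv"), row.names = FALSE)
      if (!is.null(ecg)) {
        write_wfdb(ecg, sdir)
        utils::write.csv(
          data.frame(t_sec = (seq_along(ecg$samples) - 1) / ecg$fs,
                     mv = round(ecg$samples, 6)),
          file.path(sdir, "ecg.csv"), row.names = FALSE)
      }
      truth_json <- list(
        subject_id = cfg$subject_id,
        lag_steps = cfg$lag_steps,
        coupling_strength = cfg$coupling_strength,
        baseline_mean_rr = cfg$baseline_mean_rr,
        r_times = round(rr$r_times, 6),
        truth_times = truth$times,
        truth_values = round(truth$values, 4),
        hyper = as.integer(truth$values >= 180)
      )
      jsonlite::write_json(truth_json, file.path(sdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- sdir
    }
    list(cfg = cfg, truth = truth, cgm = cgm, rr = rr, ecg = ecg, files = files)
  })
}
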
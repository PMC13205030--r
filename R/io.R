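#' Read one subject directory written by [gen_cohort()]
#'
#' Loads the WFDB ECG record (or the mirrored `ecg.csv` when no WFDB pair is
#' present), the CGM CSV (`t_min, glucose_mgdl`) and, when present, the
#' ground-truth JSON.
#'
#' @param dir subject directory.
#' @return list with `ecg` (`ecg_record`), `cgm` (`glucose_series`),
#'   `truth` (list or NULL).
#' @export
read_subject_dir <- function(dir) {
  hea <- list.files(dir, pattern = "\\.hea$", full.names = TRUE)
  ecg <- if (length(hea)) {
    read_wfdb(sub("\\.hea$", "", hea[1]))
  } else {
    csv <- utils::read.csv(file.path(dir, "ecg.csv"))
    fs <- 1 / stats::median(diff(csv$t_sec))
    ecg_record(basename(dir), fs = round(fs), samples = csv$mv, t0 = csv$t_sec[1])
  }
  cgm_df <- utils::read.csv(file.path(dir, "cgm.csv"))
  cgm <- glucose_series(cgm_df$t_min, cgm_df$glucose_mgdl, delay_corrected = FALSE)
  truth_file <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_file)) jsonlite::read_json(truth_file, simplifyVector = TRUE) else NULL
  list(ecg = ecg, cgm = cgm, truth = truth)
}

#' Lag analysis for a cohort directory on disk
#'
#' Runs preprocessing (60-s stride) and the best-lag estimation for every
#' subject directory under `cohort_dir`, returning the cohort lag table.
#'
#' @param cohort_dir directory of subject directories.
#' @param index_name representative HRV index.
#' @return the [cohort_lag_table()] of the cohort.
#' @export
lag_table_from_dir <- function(cohort_dir, index_name = "MeanNN") {
  dirs <- list.dirs(cohort_dir, recursive = FALSE)
  results <- lapply(dirs, function(d) {
    sub <- read_subject_dir(d)
    w <- preprocess_subject(sub$ecg, sub$cgm, stride_s = 60)
    feats <- compute_hrv_features(w, full = FALSE)
    tr <- hrv_trend(feats, index_name)
    infer_rows <- feats$window_start %% 120 == 0
    tr_infer <- if (sum(infer_rows) >= 20) {
      hrv_trend(feats[infer_rows, , drop = FALSE], index_name, frac = 0)
    } else NULL
    cgm <- correct_cgm_delay(sub$cgm)
    best_lag(tr, cgm, subject_id = basename(d), x_infer = tr_infer)
  })
  cohort_lag_table(results)
}
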
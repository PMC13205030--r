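#' Preprocess one subject's ECG + CGM into labeled 2-min windows
#'
#' Quality screen, 1-40 Hz zero-phase band-pass, R-peak detection,
#' segmentation at the requested stride, per-window beat extraction
#' (80 pre / 120 post samples) and labeling against the delay-corrected CGM.
#' Windows inside a screened-out 2-min block are dropped (logged).
#'
#' @param ecg an `ecg_record`.
#' @param cgm a `glucose_series` (delay-uncorrected, as read from the device;
#'   already-corrected series are used as-is).
#' @param stride_s window stride, s (120 for model inputs, 60 for trends).
#' @param peaks_override optional vector of R sample indices.
#' @param min_beats minimum NN count per window.
#' @return list of labeled windows (each also carrying `beats` and
#'   `ecg_samples`); attributes `drop_log`, `peaks`.
#' @export
preprocess_subject <- function(ecg, cgm, stride_s = 120, peaks_override = NULL,
                               min_beats = 30) {
  qs <- quality_screen(ecg)
  filtered <- bandpass_filter(ecg)
  peaks <- detect_r_peaks(filtered, peaks_override = peaks_override)
  windows <- segment_windows(filtered, peaks, stride_s = stride_s,
                             min_beats = min_beats)
  drop <- attr(windows, "drop_log")
  bad <- qs$window_start[!qs$pass]
  if (length(bad)) {
    keep <- vapply(windows, function(w) {
      !any(w$window_start < bad + 120 & w$window_start + 120 > bad)
    }, logical(1))
    for (w in windows[!keep]) {
      drop <- rbind(drop, data.frame(subject_id = w$subject_id,
                                     window_start = w$window_start,
                                     reason = "quality"))
    }
    windows <- structure(windows[keep], drop_log = drop)
  }
  windows <- lapply(windows, function(w) {
    w$beats <- extract_beats(filtered, w$peak_indices)
    i0 <- round(w$window_start * filtered$fs)
    w$ecg_samples <- filtered$samples[(i0 + 1):(i0 + round(120 * filtered$fs))]
    w
  })
  windows <- structure(windows, drop_log = drop)
  if (!cgm$delay_corrected) cgm <- correct_cgm_delay(cgm)
  windows <- label_windows(windows, cgm)
  attr(windows, "peaks") <- peaks
  windows
}

#' Per-subject HRV-glucose lag estimates for a cohort
#'
#' Runs the trend/lag analysis (1-min-stride MeanNN trend, LOWESS smoothing,
#' best-lag cross-correlation against the delay-corrected CGM) for every
#' subject of a generated cohort.
#'
#' @param cohort output of [gen_cohort()].
#' @param index_name HRV index used as the representative trajectory.
#' @param frac LOWESS span.
#' @param use_ecg detect R peaks from the rendered ECG (TRUE) or use the
#'   generator's RR series directly (FALSE; much faster, identical
#'   downstream logic).
#' @return list of `lag_result`s.
#' @export
cohort_lag_analysis <- function(cohort, index_name = "MeanNN", frac = 0.05,
                                use_ecg = FALSE) {
  lapply(cohort, function(s) {
    if (use_ecg && !is.null(s$ecg)) {
      w <- preprocess_subject(s$ecg, s$cgm, stride_s = 60)
    } else {
      ecg0 <- ecg_record(s$cfg$subject_id, 250,
                         numeric(round(s$cfg$session_minutes * 60 * 250)))
      peaks <- rpeak_series(pmax(1L, round(s$rr$r_times * 250) + 1L), 250)
      w <- segment_windows(ecg0, peaks, stride_s = 60)
    }
    feats <- compute_hrv_features(w, full = FALSE)
    tr <- hrv_trend(feats, index_name, frac = frac)
    # non-overlapping 2-min windows give the calibrated inference series
    infer_rows <- feats$window_start %% 120 == 0
    tr_infer <- if (sum(infer_rows) >= 20) {
      hrv_trend(feats[infer_rows, , drop = FALSE], index_name, frac = 0)
    } else NULL
    cgm <- if (s$cgm$delay_corrected) s$cgm else correct_cgm_delay(s$cgm)
    best_lag(tr, cgm, subject_id = s$cfg$subject_id, x_infer = tr_infer)
  })
}

#' Run the full detection pipeline on a synthetic cohort
#'
#' Stages: cohort generation, preprocessing, lag estimation and subject
#' grouping, optional filtering to the synchronous-lag subgroup, temporal
#' fold planning, dual-input cross-validation, and interpretability
#' (saliency + feature masking on each fold's test windows). Writes the
#' lag table, fold metrics, probability traces, importances and a manifest
#' to `out_dir` when given.
#'
#' @param cc a [cohort_config()].
#' @param out_dir optional output directory for CSV reports.
#' @param group_filter keep only synchronous-lag subjects before modeling.
#' @param max_beats beat-sequence cap passed to [make_dataset()].
#' @param spec_args named list of overrides for [model_spec()].
#' @param seed seed for fold planning.
#' @param verbose print progress.
#' @return list: `lag_table`, `report` (an `eval_report`), `saliency`,
#'   `importance`, `plan`, `dataset`.
#' @export
run_pipeline <- function(cc, out_dir = NULL, group_filter = TRUE,
                         max_beats = 12,
                         spec_args = list(max_epochs = 12, es_patience = 5),
                         seed = 1L, verbose = FALSE) {
  cohort <- gen_cohort(cc, render_ecg = TRUE)
  lags <- cohort_lag_analysis(cohort)
  lag_table <- cohort_lag_table(lags)
  keep <- if (group_filter) lag_table$subject_id[lag_table$group == "synchronous"]
          else lag_table$subject_id
  if (!length(keep)) stop("group filter removed every subject")
  windows <- list()
  for (s in cohort) {
    if (!s$cfg$subject_id %in% keep) next
    w <- preprocess_subject(s$ecg, s$cgm, stride_s = 120)
    windows <- c(windows, w)
  }
  windows <- fix_beat_count(windows)
  dataset <- make_dataset(windows, max_beats = max_beats)
  plan <- plan_folds(dataset$features, seed = seed)
  spec <- do.call(model_spec, c(list(n_beats = dim(dataset$beats)[2], seed = seed),
                                spec_args))
  report <- cross_validate(dataset, plan, spec, verbose = verbose)
  # interpretability on each fold's test windows, averaged over folds
  sal_acc <- NULL; imp_acc <- NULL
  for (f in seq_len(plan$n_folds)) {
    mf <- materialize_fold(plan, f)
    st <- subject_stats(dataset$features, train_mask = !seq_along(dataset$labels) %in% mf$test)
    X <- as.matrix(normalize_hrv(dataset$features, st)[, HRV_INDEX_NAMES])
    X[!is.finite(X)] <- 0
    m <- report$models[[f]]
    sal <- saliency_profile(m, dataset$beats[mf$test, , , drop = FALSE],
                            X[mf$test, , drop = FALSE])
    imp <- feature_masking(m, dataset$beats[mf$test, , , drop = FALSE],
                           X[mf$test, , drop = FALSE])
    sal_acc <- rbind(sal_acc, sal$mean)
    imp_acc <- rbind(imp_acc, imp$importance[match(HRV_INDEX_NAMES, imp$index)])
  }
  saliency <- list(mean = colMeans(sal_acc), per_fold = sal_acc)
  importance <- data.frame(index = HRV_INDEX_NAMES, importance = colMeans(imp_acc))
  importance <- importance[order(-importance$importance), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(lag_table, file.path(out_dir, "lag_table.csv"), row.names = FALSE)
    utils::write.csv(report$folds, file.path(out_dir, "fold_metrics.csv"), row.names = FALSE)
    utils::write.csv(report$traces, file.path(out_dir, "probability_traces.csv"), row.names = FALSE)
    utils::write.csv(importance, file.path(out_dir, "feature_importance.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample = seq_along(saliency$mean) - 81,
                                saliency = saliency$mean),
                     file.path(out_dir, "saliency_profile.csv"), row.names = FALSE)
    cfg_path <- file.path(out_dir, "manifest.json")
    manifest <- list(
      cohort_config = unclass(cc)[setdiff(names(unclass(cc)), "lag_distribution")],
      lag_distribution = cc$lag_distribution,
      seed = seed, max_beats = max_beats, spec_args = spec_args,
      group_filter = group_filter,
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("glycohrv"))
    )
    jsonlite::write_json(manifest, cfg_path, auto_unbox = TRUE, digits = NA)
    manifest_hash <- unname(tools::md5sum(cfg_path))
    writeLines(manifest_hash, file.path(out_dir, "manifest.md5"))
  }
  list(lag_table = lag_table, report = report, saliency = saliency,
       importance = importance, plan = plan, dataset = dataset)
}
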
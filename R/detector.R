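#' Assemble a model-ready dataset from labeled windows
#'
#' Stacks the per-window beat matrices into an `(n, n_beats, 200)` array and
#' computes the raw (unnormalized) HRV feature table. `max_beats` optionally
#' caps the beats per window (the first `max_beats` chronologically) to bound
#' compute; windows must already share a common beat count
#' (see [fix_beat_count()]).
#'
#' @param windows labeled windows carrying `beats` matrices.
#' @param max_beats optional cap on beats per window.
#' @return a `glyco_dataset`: `beats`, `features` (raw), `labels`,
#'   `subject_id`, `window_start`.
#' @export
make_dataset <- function(windows, max_beats = NULL) {
  counts <- vapply(windows, function(w) nrow(w$beats), integer(1))
  if (length(unique(counts)) != 1) stop("windows must share one beat count; run fix_beat_count()")
  TT <- counts[1]
  if (!is.null(max_beats)) TT <- min(TT, max_beats)
  n <- length(windows)
  L <- ncol(windows[[1]]$beats)
  beats <- array(0, c(n, TT, L))
  for (i in seq_len(n)) beats[i, , ] <- windows[[i]]$beats[seq_len(TT), ]
  features <- compute_hrv_features(windows)
  structure(list(
    beats = beats,
    features = features,
    labels = vapply(windows, `[[`, character(1), "label"),
    subject_id = features$subject_id,
    window_start = features$window_start
  ), class = "glyco_dataset")
}

#' Classification metrics for probability predictions
#'
#' Confusion matrix at a 0.5 threshold on the hyperglycemia probability;
#' accuracy, precision, sensitivity (hyperglycemia recall), specificity, F1,
#' and AUC-ROC computed by the rank (Mann-Whitney) statistic, which equals
#' the trapezoidal area over all thresholds with ties counted half. AUC is
#' `NA` for a one-class test set; precision and F1 are 0 when undefined.
#'
#' @param p_hyper predicted hyperglycemia probabilities.
#' @param labels true labels ("hyperglycemia"/"euglycemia").
#' @param threshold decision threshold.
#' @return named vector of the six metrics.
#' @export
evaluate_predictions <- function(p_hyper, labels, threshold = 0.5) {
  stopifnot(length(p_hyper) == length(labels))
  y <- labels == "hyperglycemia"
  pred <- p_hyper >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (precision + sens > 0) 2 * precision * sens / (precision + sens) else 0
  auc <- if (any(y) && any(!y)) {
    r <- rank(p_hyper)
    (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  } else NA_real_
  c(accuracy = (tp + tn) / length(y), precision = precision,
    sensitivity = sens, specificity = spec, f1 = f1, auc = auc)
}

#' Summarize fold-wise metrics like a cross-validation report
#'
#' @param fold_metrics data.frame of per-fold metrics (one row per fold).
#' @return the table with `AVG` (mean) and `STD` (sample sd, n - 1) rows
#'   appended.
#' @export
fold_summary <- function(fold_metrics) {
  m <- fold_metrics[, setdiff(names(fold_metrics), "fold"), drop = FALSE]
  rbind(
    cbind(fold = as.character(fold_metrics$fold), m),
    cbind(fold = "AVG", as.data.frame(as.list(colMeans(m, na.rm = TRUE)))),
    cbind(fold = "STD", as.data.frame(as.list(apply(m, 2, stats::sd, na.rm = TRUE))))
  )
}

#' Temporal-split cross-validation of the detector
#'
#' For each fold: per-subject normalization statistics are computed on the
#' training blocks only and applied to both sides (no leakage), a fresh model
#' is trained and evaluated on the held-out blocks. Reports fold-wise
#' metrics with mean and sample sd, and the out-of-sample hyperglycemia
#' probability trace of every window (each window is test exactly once).
#'
#' @param dataset a `glyco_dataset`.
#' @param plan a `fold_plan` over the dataset rows.
#' @param spec a [model_spec()]; its `inputs` field selects the ablation arm.
#' @param verbose print fold progress.
#' @return an `eval_report`: `folds` (metrics + AVG/STD), `traces`
#'   (subject, window_start, label, p_hyper, fold), `models`.
#' @export
cross_validate <- function(dataset, plan, spec, verbose = FALSE) {
  stopifnot(inherits(dataset, "glyco_dataset"), inherits(plan, "fold_plan"))
  n <- length(dataset$labels)
  fold_rows <- list()
  traces <- data.frame()
  models <- list()
  for (f in seq_len(plan$n_folds)) {
    mf <- materialize_fold(plan, f)
    st <- subject_stats(dataset$features, train_mask = seq_len(n) %in% mf$train)
    feats <- normalize_hrv(dataset$features, st)
    X <- as.matrix(feats[, HRV_INDEX_NAMES])
    X[!is.finite(X)] <- 0   # explicit imputation at the z-score center
    sp <- spec; sp$seed <- spec$seed + f
    model <- build_model(sp)
    model <- train_model(model,
                         beats = dataset$beats[mf$train, , , drop = FALSE],
                         hrv = X[mf$train, , drop = FALSE],
                         labels = dataset$labels[mf$train],
                         verbose = verbose)
    bb <- if (sp$inputs != "hrv") dataset$beats[mf$test, , , drop = FALSE] else NULL
    hh <- if (sp$inputs != "ecg") X[mf$test, , drop = FALSE] else NULL
    probs <- predict(model, bb, hh)
    met <- evaluate_predictions(probs[, 2], dataset$labels[mf$test])
    fold_rows[[f]] <- cbind(data.frame(fold = f), as.data.frame(as.list(met)))
    traces <- rbind(traces, data.frame(
      subject_id = dataset$subject_id[mf$test],
      window_start = dataset$window_start[mf$test],
      label = dataset$labels[mf$test],
      p_hyper = probs[, 2], fold = f))
    models[[f]] <- model
    if (verbose) message(sprintf("fold %d: acc %.3f auc %.3f", f, met["accuracy"], met["auc"]))
  }
  fm <- do.call(rbind, fold_rows)
  structure(list(folds = fold_summary(fm), fold_metrics = fm,
                 traces = traces[order(traces$subject_id, traces$window_start), ],
                 models = models),
            class = "eval_report")
}
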
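#' Gradient saliency profile over beat morphology
#'
#' Saliency of input sample `i` is `|d y_c / d x_i|` where `y_c` is the
#' pre-softmax hyperglycemia logit. Absolute gradients are averaged over the
#' beats within each window, then mean and sd are taken over windows, giving
#' a 200-point profile aligned to the beat frame (samples 1..200 correspond
#' to R-80 .. R+119). Computed in evaluation mode (running batch-norm
#' statistics, no dropout).
#'
#' @param model a trained `glyco_model` using the ECG branch.
#' @param beats `(B, n_beats, 200)` array.
#' @param hrv `(B, 31)` normalized features (NULL for an ECG-only model).
#' @return a `saliency_profile`: `mean`, `sd` (length 200), and `mean_beat`
#'   (the average beat waveform for plotting).
#' @export
saliency_profile <- function(model, beats, hrv = NULL) {
  if (model$spec$inputs == "hrv") stop("model has no beat-morphology branch")
  stopifnot(dim(beats)[1] >= 1)
  if (!is.null(hrv)) hrv[!is.finite(hrv)] <- 0
  fw <- model_forward(model, beats, hrv, training = FALSE)
  dlog <- matrix(0, nrow(fw$logits), ncol(fw$logits))
  dlog[, 2] <- 1   # hyperglycemia logit
  bw <- model_backward(model, fw$cache, dlog)
  if (is.null(bw$d_beats)) stop("gradient unavailable")
  sal <- abs(bw$d_beats)                       # (B, T, 200)
  per_window <- apply(sal, c(1, 3), mean)      # mean over beats -> (B, 200)
  structure(list(
    mean = colMeans(per_window),
    sd = apply(per_window, 2, stats::sd),
    mean_beat = apply(beats, 3, mean)
  ), class = "saliency_profile")
}

#' One-at-a-time HRV feature-masking importance
#'
#' For each index `j`, feature `j` is replaced by `mask_value` (0, the
#' z-score center, i.e. roughly the subject mean) and the drop in the
#' hyperglycemia softmax probability `Delta S_j = f(x) - f(x_masked)` is
#' averaged over windows. Masking is one-at-a-time, so importances are
#' independent of evaluation order.
#'
#' @param model a trained `glyco_model` using the HRV branch.
#' @param beats `(B, n_beats, 200)` array (NULL for an HRV-only model).
#' @param hrv `(B, 31)` normalized features.
#' @param mask_value value substituted for the masked feature.
#' @return data.frame `index`, `importance`, sorted descending.
#' @export
feature_masking <- function(model, beats, hrv, mask_value = 0) {
  if (model$spec$inputs == "ecg") stop("model has no HRV branch")
  hrv[!is.finite(hrv)] <- 0
  base <- model_forward(model, beats, hrv, training = FALSE)$probs[, 2]
  imp <- vapply(seq_len(ncol(hrv)), function(j) {
    hm <- hrv
    hm[, j] <- mask_value
    mean(base - model_forward(model, beats, hm, training = FALSE)$probs[, 2])
  }, numeric(1))
  out <- data.frame(index = HRV_INDEX_NAMES[seq_len(ncol(hrv))], importance = imp)
  out[order(-out$importance), ]
}
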
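# Canonical order of the 31 indices. Every feature table and model input
# uses exactly this ordering.
HRV_INDEX_NAMES <- c(
  "MeanNN", "SDNN", "RMSSD", "pNN50", "pNN20", "MedianNN",
  "SD1", "SD2", "SD1SD2", "ShanEn", "FuzzyEn", "MSEn", "CMSEn", "RCMSEn",
  "CD", "HFD", "KFD",
  "VLF", "LF", "HF", "LFHF", "VHF", "TotalPower",
  "RRI_mobility", "ECG_mobility", "RRI_complexity", "ECG_complexity",
  "RRI_skewness", "ECG_skewness", "RRI_kurtosis", "ECG_kurtosis"
)

# Indices rescaled by the subject's mean NN (Eq.-1 style); everything else is
# z-scored per subject.
HRV_MEANNN_NORM <- c("SDNN", "RMSSD", "SD1", "SD2")

#' Canonical HRV index names
#' @return character vector of the 31 index names in canonical order.
#' @export
hrv_index_names <- function() HRV_INDEX_NAMES

# -- time domain -------------------------------------------------------------

#' Time-domain HRV indices
#'
#' @param nn_ms NN intervals, ms (>= 2 values).
#' @return named vector: MeanNN, SDNN (sample sd), RMSSD, pNN50, pNN20 (in
#'   percent of successive differences exceeding 50/20 ms), MedianNN.
#' @export
time_domain <- function(nn_ms) {
  if (length(nn_ms) < 2) stop("need at least 2 NN intervals")
  d <- diff(nn_ms)
  c(MeanNN = mean(nn_ms),
    SDNN = stats::sd(nn_ms),
    RMSSD = sqrt(mean(d^2)),
    pNN50 = 100 * mean(abs(d) > 50),
    pNN20 = 100 * mean(abs(d) > 20),
    MedianNN = stats::median(nn_ms))
}

# -- Poincare ----------------------------------------------------------------

#' Poincare dispersions SD1, SD2
#'
#' `SD1^2` is half the (uncentered) mean squared successive difference, making
#' `SD1 = RMSSD / sqrt(2)` an exact identity; `SD2^2 = 2 * var(NN) - SD1^2`
#' (sample variance), making `SD1^2 + SD2^2 = 2 * SDNN^2` exact. The ratio is
#' `NA` when SD2 is zero.
#'
#' @param nn_ms NN intervals, ms (>= 3 values).
#' @return named vector SD1, SD2, SD1SD2.
#' @export
poincare <- function(nn_ms) {
  if (length(nn_ms) < 3) stop("need at least 3 NN intervals")
  d <- diff(nn_ms)
  sd1 <- sqrt(mean(d^2) / 2)
  sd2sq <- 2 * stats::var(nn_ms) - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  c(SD1 = sd1, SD2 = sd2,
    SD1SD2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

# -- entropies ---------------------------------------------------------------

#' Shannon entropy of the NN histogram
#'
#' 10 equal-width bins over the window's NN range; base-2 logarithm. A
#' constant series occupies one bin and returns 0.
#'
#' @param nn_ms NN intervals, ms.
#' @param bins number of bins.
#' @export
shannon_entropy <- function(nn_ms, bins = 10) {
  rng <- range(nn_ms)
  if (diff(rng) == 0) return(0)
  h <- tabulate(pmin(bins, findInterval(nn_ms, seq(rng[1], rng[2], length.out = bins + 1),
                                        rightmost.closed = TRUE)), bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Fuzzy entropy
#'
#' FuzzyEn(m, r) with baseline-removed templates, Chebyshev distance and the
#' exponential membership `exp(-d^n / r)` (Chen's formulation); `r` defaults
#' to `0.2 * sd(x)`.
#'
#' @param x series.
#' @param m embedding dimension.
#' @param r tolerance (absolute); default `0.2 * sd(x)`.
#' @param n membership exponent.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x), n = 2) {
  N <- length(x)
  if (N < m + 2) return(NA_real_)
  if (r == 0) return(0)
  phi <- function(mm) {
    nv <- N - mm + 1
    tmpl <- matrix(0, nv, mm)
    for (j in seq_len(mm)) tmpl[, j] <- x[j:(j + nv - 1)]
    tmpl <- tmpl - rowMeans(tmpl)
    tot <- 0
    for (i in seq_len(nv - 1)) {
      d <- abs(sweep(tmpl[(i + 1):nv, , drop = FALSE], 2, tmpl[i, ]))
      dmax <- if (ncol(d) > 1) apply(d, 1, max) else as.numeric(d)
      tot <- tot + sum(exp(-dmax^n / r))
    }
    2 * tot / ((nv - 1) * nv)
  }
  # exclude the last template at dimension m so both sums use N - m vectors
  p_m <- phi(m)
  p_m1 <- phi(m + 1)
  if (p_m1 == 0 || p_m == 0) return(NA_real_)
  log(p_m) - log(p_m1)
}

# Sample entropy match counts: returns c(B, A) = template pairs matching at
# dimension m and m + 1 (Chebyshev, self-matches excluded).
sampen_counts <- function(x, m, r) {
  N <- length(x)
  nv <- N - m
  if (nv < 2) return(c(0, 0))
  B <- 0; A <- 0
  for (i in seq_len(nv - 1)) {
    dm <- rep(0, nv - i)
    for (j in seq_len(m)) {
      dm <- pmax(dm, abs(x[(i + 1):(nv) + j - 1] - x[i + j - 1]))
    }
    hit <- dm <= r
    B <- B + sum(hit)
    if (any(hit)) {
      dm1 <- abs(x[(i + 1):nv + m] - x[i + m])
      A <- A + sum(hit & pmax(dm, dm1) <= r)
    }
  }
  c(B = B, A = A)
}

coarse_grain <- function(x, scale, offset = 1) {
  n <- floor((length(x) - offset + 1) / scale)
  if (n < 1) return(numeric(0))
  idx <- offset + rep(seq_len(n) - 1, each = scale) * scale + seq_len(scale) - 1
  colMeans(matrix(x[idx], nrow = scale))
}

#' Multiscale sample entropies
#'
#' Sample entropy (m = 2, Chebyshev, self-matches excluded) of coarse-grained
#' series at scales 1..3, aggregated by the mean over scales. `r` is fixed at
#' `0.2 * sd` of the original series for all scales. Three variants: plain
#' multiscale (`MSEn`, one coarse-graining per scale), composite (`CMSEn`,
#' entropy averaged over all coarse-graining offsets), and refined composite
#' (`RCMSEn`, match counts pooled over offsets before the log ratio).
#' Scales with no matches yield `NA` and are dropped from the mean (all-`NA`
#' propagates).
#'
#' @param x series (>= 30 values recommended).
#' @param m embedding dimension.
#' @param scales integer scales.
#' @param r tolerance.
#' @return named vector MSEn, CMSEn, RCMSEn.
#' @export
multiscale_entropy <- function(x, m = 2, scales = 1:3, r = 0.2 * stats::sd(x)) {
  if (r == 0) return(c(MSEn = NA_real_, CMSEn = NA_real_, RCMSEn = NA_real_))
  mse <- cmse <- rcmse <- rep(NA_real_, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    offs <- seq_len(s)
    ents <- rep(NA_real_, s)
    Bt <- At <- 0
    for (o in offs) {
      y <- coarse_grain(x, s, o)
      cnt <- sampen_counts(y, m, r)
      Bt <- Bt + cnt[1]; At <- At + cnt[2]
      if (cnt[1] > 0 && cnt[2] > 0) ents[o] <- -log(cnt[2] / cnt[1])
    }
    mse[si] <- ents[1]
    if (any(!is.na(ents))) cmse[si] <- mean(ents, na.rm = TRUE)
    if (Bt > 0 && At > 0) rcmse[si] <- -log(At / Bt)
  }
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  c(MSEn = mn(mse), CMSEn = mn(cmse), RCMSEn = mn(rcmse))
}

#' Entropy indices for one window
#' @param nn_ms NN intervals (>= 30).
#' @return named vector ShanEn, FuzzyEn, MSEn, CMSEn, RCMSEn.
#' @export
entropy_indices <- function(nn_ms) {
  if (length(nn_ms) < 30) stop("need at least 30 NN intervals")
  c(ShanEn = shannon_entropy(nn_ms),
    FuzzyEn = fuzzy_entropy(nn_ms),
    multiscale_entropy(nn_ms))
}

# -- fractal -----------------------------------------------------------------

#' Grassberger-Procaccia correlation dimension
#'
#' Embedding dimension 2, delay 1. The correlation sum `C(r)` is evaluated on
#' log-spaced radii between the 10th and 50th percentile of pairwise
#' Chebyshev distances and the dimension is the least-squares slope of
#' `log C` vs `log r`.
#'
#' @param x series.
#' @param m embedding dimension.
#' @export
correlation_dimension <- function(x, m = 2) {
  n <- length(x) - m + 1
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  emb <- sapply(seq_len(m), function(j) x[j:(j + n - 1)])
  d <- as.numeric(stats::dist(emb, method = "maximum"))
  d <- d[d > 0]
  if (length(d) < 10) return(NA_real_)
  qs <- stats::quantile(d, c(0.1, 0.5))
  if (qs[1] <= 0 || qs[2] <= qs[1]) return(NA_real_)
  rs <- exp(seq(log(qs[1]), log(qs[2]), length.out = 8))
  cr <- vapply(rs, function(r) mean(d <= r), numeric(1))
  keep <- cr > 0
  if (sum(keep) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(log(cr[keep]) ~ log(rs[keep])))[2])
}

#' Higuchi fractal dimension
#' @param x series.
#' @param k_max maximum delay.
#' @export
higuchi_fd <- function(x, k_max = 10) {
  N <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_ <- vapply(seq_len(k), function(m0) {
      idx <- seq(m0, N, by = k)
      if (length(idx) < 2) return(NA_real_)
      (sum(abs(diff(x[idx]))) * (N - 1) / (floor((N - m0) / k) * k)) / k
    }, numeric(1))
    mean(lm_, na.rm = TRUE)
  }, numeric(1))
  k <- seq_len(k_max)
  unname(-stats::coef(stats::lm(log(lk) ~ log(k)))[2])
}

#' Katz fractal dimension
#'
#' `KFD = log10(n) / (log10(n) + log10(d / L))` with `L` the total path
#' length, `d` the maximum distance from the first point and `n` the number
#' of steps. A straight line gives exactly 1.
#'
#' @param x series.
#' @export
katz_fd <- function(x) {
  n <- length(x) - 1
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (L == 0 || d == 0) return(NA_real_)
  log10(n) / (log10(n) + log10(d / L))
}

#' Fractal indices for one window
#' @param nn_ms NN intervals (>= 30).
#' @return named vector CD, HFD, KFD.
#' @export
fractal_indices <- function(nn_ms) {
  if (length(nn_ms) < 30) stop("need at least 30 NN intervals")
  if (stats::sd(nn_ms) == 0) {
    return(c(CD = NA_real_, HFD = NA_real_, KFD = NA_real_))
  }
  c(CD = correlation_dimension(nn_ms),
    HFD = higuchi_fd(nn_ms),
    KFD = katz_fd(nn_ms))
}

# -- frequency domain (Lomb-Scargle) -----------------------------------------

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic (Press) normalization computed directly from the definition; the
#' returned `power` is scaled so that summing `power` over the natural
#' frequency grid (oversampling accounted for) partitions the series
#' variance, giving band powers in ms^2.
#'
#' @param t sample times, s.
#' @param x values (centered internally).
#' @param freq frequencies, Hz.
#' @param oversample oversampling factor the grid was built with.
#' @return data.frame `freq`, `power`.
#' @export
lomb_scargle <- function(t, x, freq, oversample = 4) {
  x <- x - mean(x)
  n <- length(x)
  pw <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  # scale: sum over the natural grid ~ variance -> ms^2 band powers
  data.frame(freq = freq, power = pw * 2 / (n * oversample))
}

#' Spectral band powers of the NN tachogram
#'
#' Lomb-Scargle periodogram of the unevenly sampled tachogram (no
#' interpolation or resampling). Powers are integrated over VLF (< 0.04 Hz),
#' LF (0.04-0.15), HF (0.15-0.4) and VHF (> 0.4 Hz up to half the mean beat
#' rate); each grid frequency belongs to exactly one band so the four bands
#' partition TotalPower. The LF/HF ratio is `NA` when HF is zero.
#'
#' @param beat_times beat times, s.
#' @param nn_ms NN intervals, ms (same length).
#' @param oversample frequency oversampling factor.
#' @return named vector VLF, LF, HF, LFHF, VHF, TotalPower (ms^2).
#' @export
lsp_bands <- function(beat_times, nn_ms, oversample = 4) {
  if (length(nn_ms) < 30) stop("need at least 30 NN intervals")
  span <- diff(range(beat_times))
  f_hi <- 1000 / (2 * mean(nn_ms))   # half the mean beat rate, Hz
  df <- 1 / (oversample * span)
  freq <- seq(df, f_hi, by = df)
  if (stats::sd(nn_ms) == 0) {
    return(c(VLF = 0, LF = 0, HF = 0, LFHF = NA_real_, VHF = 0, TotalPower = 0))
  }
  ls <- lomb_scargle(beat_times, nn_ms, freq, oversample)
  band <- cut(ls$freq, c(0, 0.04, 0.15, 0.4, Inf),
              labels = c("VLF", "LF", "HF", "VHF"), right = FALSE)
  p <- vapply(c("VLF", "LF", "HF", "VHF"),
              function(b) sum(ls$power[band == b]), numeric(1))
  c(VLF = unname(p["VLF"]), LF = unname(p["LF"]), HF = unname(p["HF"]),
    LFHF = if (p["HF"] > 0) unname(p["LF"] / p["HF"]) else NA_real_,
    VHF = unname(p["VHF"]), TotalPower = sum(p))
}

# -- Hjorth / statistical ----------------------------------------------------

hjorth_mobility <- function(x) {
  v <- mean((x - mean(x))^2)
  if (v == 0) return(NA_real_)
  d <- diff(x)
  sqrt(mean((d - mean(d))^2) / v)
}

#' Hjorth and distributional statistics of RR and ECG
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))` (population moments), complexity
#' is `mobility(diff(x)) / mobility(x)`; skewness is Fisher `g1` and kurtosis
#' is excess `g2`, for the NN series and the raw ECG samples of the window.
#'
#' @param nn_ms NN intervals.
#' @param ecg_window raw ECG samples of the same window.
#' @return named vector of 8 indices.
#' @export
hjorth_stats <- function(nn_ms, ecg_window) {
  stopifnot(length(nn_ms) > 0, length(ecg_window) > 0)
  one <- function(x) {
    mob <- hjorth_mobility(x)
    cmp <- if (is.na(mob) || length(x) < 3) NA_real_ else {
      m2 <- hjorth_mobility(diff(x))
      if (is.na(m2)) NA_real_ else m2 / mob
    }
    c(mob, cmp, moment_skewness(x), moment_kurtosis(x))
  }
  r <- one(nn_ms); e <- one(ecg_window)
  c(RRI_mobility = r[1], ECG_mobility = e[1],
    RRI_complexity = r[2], ECG_complexity = e[2],
    RRI_skewness = r[3], ECG_skewness = e[3],
    RRI_kurtosis = r[4], ECG_kurtosis = e[4])
}

# -- assembly & normalization ------------------------------------------------

#' Assemble the 31-index HRV vector for one window
#'
#' Computes all parts and returns them in the fixed canonical order (see
#' [hrv_index_names()]); missing values are carried explicitly as `NA`.
#'
#' @param nn_ms NN intervals of the window.
#' @param beat_times beat times of the window, s.
#' @param ecg_window raw ECG samples of the window.
#' @return named numeric vector of length 31 with attribute
#'   `normalized = FALSE`.
#' @export
assemble_hrv_vector <- function(nn_ms, beat_times, ecg_window) {
  v <- c(time_domain(nn_ms), poincare(nn_ms), entropy_indices(nn_ms),
         fractal_indices(nn_ms), lsp_bands(beat_times, nn_ms),
         hjorth_stats(nn_ms, ecg_window))
  if (!identical(names(v), HRV_INDEX_NAMES)) {
    stop("assembled vector does not match the canonical 31-index layout")
  }
  structure(v, normalized = FALSE)
}

#' Per-window HRV feature table for a window list
#'
#' @param windows labeled windows (each with `nn_ms`, `beat_times`, and
#'   either `ecg_samples` or `beats` to supply raw ECG amplitudes).
#' @param full compute all 31 indices (TRUE) or only the cheap time-domain
#'   six (FALSE; used by the trend/lag stage, which needs MeanNN only).
#' @return data.frame: `subject_id`, `window_start`, `glucose`, `label`, then
#'   the indices in canonical order. Attribute `normalized = FALSE`.
#' @export
compute_hrv_features <- function(windows, full = TRUE) {
  rows <- lapply(windows, function(w) {
    v <- if (full) {
      ecg_w <- w$ecg_samples %||% as.numeric(t(w$beats))
      assemble_hrv_vector(w$nn_ms, w$beat_times, ecg_w)
    } else time_domain(w$nn_ms)
    cbind(data.frame(subject_id = w$subject_id,
                     window_start = w$window_start,
                     glucose = w$glucose %||% NA_real_,
                     label = w$label %||% NA_character_),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  attr(out, "normalized") <- FALSE
  out
}

#' Per-subject normalization statistics
#'
#' For each subject: the mean NN (mean of the window MeanNN values) used by
#' the mean-NN rescaling, and the per-index mean/sd used by the z-score rule.
#' When `train_mask` is given, statistics come from those rows only (the
#' training-visible windows inside cross-validation).
#'
#' @param features a feature table from [compute_hrv_features()].
#' @param train_mask optional logical mask of training rows.
#' @return named list per subject: `mean_nn`, `mu`, `sigma`.
#' @export
subject_stats <- function(features, train_mask = NULL) {
  if (is.null(train_mask)) train_mask <- rep(TRUE, nrow(features))
  sub <- features[train_mask, , drop = FALSE]
  out <- lapply(split(sub, sub$subject_id), function(d) {
    m <- as.matrix(d[, HRV_INDEX_NAMES, drop = FALSE])
    list(mean_nn = mean(m[, "MeanNN"], na.rm = TRUE),
         mu = colMeans(m, na.rm = TRUE),
         sigma = apply(m, 2, stats::sd, na.rm = TRUE))
  })
  out
}

#' Subject-wise normalization of HRV features
#'
#' SDNN, RMSSD, SD1 and SD2 are rescaled to `(raw / meanNN) * 100`; every
#' other index is z-scored with the subject's mean and sd (`sigma = 0` or
#' non-finite values give 0). Normalizing an already normalized table is an
#' error.
#'
#' @param features feature table from [compute_hrv_features()].
#' @param stats per-subject statistics from [subject_stats()]; defaults to
#'   statistics over the whole table.
#' @return the normalized feature table (`normalized = TRUE`).
#' @export
normalize_hrv <- function(features, stats = subject_stats(features)) {
  if (isTRUE(attr(features, "normalized"))) stop("features are already normalized")
  out <- features
  for (sid in unique(features$subject_id)) {
    st <- stats[[sid]]
    if (is.null(st)) stop(sprintf("no statistics for subject '%s'", sid))
    rows <- which(features$subject_id == sid)
    for (idx in HRV_INDEX_NAMES) {
      x <- features[rows, idx]
      if (idx %in% HRV_MEANNN_NORM) {
        out[rows, idx] <- x / st$mean_nn * 100
      } else {
        s <- st$sigma[idx]
        # sigma = 0 maps to 0; NA inputs stay NA (imputed explicitly, and
        # only at model-input assembly)
        z <- if (!is.finite(s) || s == 0) ifelse(is.na(x), NA_real_, 0) else (x - st$mu[idx]) / s
        out[rows, idx] <- z
      }
    }
  }
  attr(out, "normalized") <- TRUE
  out
}
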
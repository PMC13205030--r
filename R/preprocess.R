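# -- filtering ---------------------------------------------------------------

poly_from_roots <- function(r) {
  p <- 1
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog Butterworth prototype, lowpass-to-bandpass transform with frequency
#' pre-warping, bilinear transform. `order` is the prototype order (the
#' digital filter has `2 * order` poles).
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order prototype order.
#' @return list with numerator `b` and denominator `a` (a[1] = 1).
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  stopifnot(low > 0, high > low, high < fs / 2)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  s <- p_lp * bw / 2
  p_bp <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  gain <- bw^order
  fs2 <- 2 * fs
  zd <- (fs2 + z_bp) / (fs2 - z_bp)
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  gd <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  zd <- c(zd, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a / a[1])
}

# Single-pass IIR filter with zero initial state (a[1] = 1).
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  } else v
}

# Zero-phase (forward-backward) filtering with odd-reflection padding. The
# first padded value is subtracted before each pass; a band-pass has zero DC
# gain so this changes nothing at steady state but removes start-up steps.
filtfilt_bp <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  p <- min(n - 1, padlen %||% max(3 * (length(a) - 1), 750))
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  xp <- c(left, x, right)
  y <- iir_filter(b, a, xp - xp[1])
  y <- rev(y)
  y <- iir_filter(b, a, y - y[1])
  y <- rev(y)
  y[(p + 1):(p + n)]
}

#' Band-pass filter an ECG record (zero phase)
#'
#' 4th-order Butterworth, 1-40 Hz by default, applied forward-backward so that
#' R-peak positions are not displaced. Output length equals input length; the
#' DC component is removed.
#'
#' @param ecg an `ecg_record` with `fs > 80`.
#' @param low,high band edges in Hz.
#' @param order prototype order.
#' @return the filtered `ecg_record`.
#' @export
bandpass_filter <- function(ecg, low = 1, high = 40, order = 4) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (ecg$fs <= 80) stop("sampling rate must exceed 80 Hz (passband below Nyquist)")
  f <- butter_bandpass(low, high, ecg$fs, order)
  out <- ecg
  out$samples <- filtfilt_bp(f$b, f$a, ecg$samples)
  out
}

# -- quality screening -------------------------------------------------------

longest_run <- function(flag) {
  if (!length(flag)) return(0L)
  r <- rle(flag)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Stand-in signal-quality screen
#'
#' Replaces the recorder's proprietary SQI with simple per-window rules: a
#' 2-min window is flagged if it contains any non-finite samples, a flatline
#' run longer than 1 s, clipping (a run of >= 5 samples pinned at the window
#' extreme), amplitude kurtosis above `kurt_max` (impulsive artifacts), or a
#' first-difference-to-amplitude sd ratio above `noise_ratio_max` (broadband
#' noise; white noise approaches sqrt(2)).
#'
#' @param ecg an `ecg_record`.
#' @param window_s window length, s.
#' @param kurt_max excess-kurtosis threshold.
#' @param noise_ratio_max sd(diff(x))/sd(x) threshold.
#' @return data.frame with `window_start` (s), `pass`, `reason`.
#' @export
quality_screen <- function(ecg, window_s = 120, kurt_max = 100, noise_ratio_max = 0.8) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!length(ecg$samples)) stop("empty record")
  fs <- ecg$fs
  wlen <- round(window_s * fs)
  starts <- seq(0, length(ecg$samples) - wlen, by = wlen)
  res <- lapply(starts, function(s0) {
    x <- ecg$samples[(s0 + 1):(s0 + wlen)]
    if (any(!is.finite(x))) return(list(pass = FALSE, reason = "nonfinite"))
    if (longest_run(c(FALSE, abs(diff(x)) < 1e-12)) > fs) {
      return(list(pass = FALSE, reason = "flatline"))
    }
    if (longest_run(x == max(x)) >= 5 || longest_run(x == min(x)) >= 5) {
      return(list(pass = FALSE, reason = "clipping"))
    }
    if (isTRUE(moment_kurtosis(x) > kurt_max)) {
      return(list(pass = FALSE, reason = "kurtosis"))
    }
    if (stats::sd(x) > 0 && stats::sd(diff(x)) / stats::sd(x) > noise_ratio_max) {
      return(list(pass = FALSE, reason = "noise"))
    }
    list(pass = TRUE, reason = "")
  })
  data.frame(window_start = starts / fs,
             pass = vapply(res, `[[`, logical(1), "pass"),
             reason = vapply(res, `[[`, character(1), "reason"))
}

# -- R-peak detection --------------------------------------------------------

#' Construct an R-peak series
#' @param indices 1-based sample positions of R peaks.
#' @param fs sampling rate, Hz.
#' @param t0 record start time, s.
#' @export
rpeak_series <- function(indices, fs, t0 = 0) {
  indices <- as.integer(indices)
  if (length(indices) && any(diff(indices) <= 0)) stop("peak indices must be strictly increasing")
  structure(list(indices = indices, times = (indices - 1) / fs + t0, fs = fs),
            class = "rpeak_series")
}

#' Detect R peaks (Pan-Tompkins)
#'
#' Classic Pan-Tompkins pipeline: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, adaptive signal/noise
#' thresholds with a missed-beat search-back, then refinement of each
#' detection to the local maximum of the input signal. All stages are
#' zero-phase/centered so detected positions align with the waveform. A
#' `peaks_override` (vector of 1-based sample indices) replaces detection
#' entirely, standing in for manual correction.
#'
#' @param ecg a (band-pass filtered) `ecg_record`.
#' @param method currently only `"pan_tompkins"`.
#' @param peaks_override optional integer vector of R sample indices.
#' @return an `rpeak_series`.
#' @export
detect_r_peaks <- function(ecg, method = "pan_tompkins", peaks_override = NULL) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!is.null(peaks_override)) {
    return(rpeak_series(sort(unique(as.integer(peaks_override))), ecg$fs, ecg$t0))
  }
  method <- match.arg(method, "pan_tompkins")
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) < fs) stop(sprintf("record '%s' too short for peak detection", ecg$subject_id))
  f <- butter_bandpass(5, 15, fs, order = 2)
  xf <- filtfilt_bp(f$b, f$a, x)
  der <- as.numeric(stats::filter(xf, c(2, 1, 0, -1, -2) / 8, sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  w <- round(0.150 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  # candidate peaks: local maxima of the integrated signal
  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] & mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  refractory <- round(0.2 * fs)
  init <- mwi[1:min(n, 2 * fs)]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_avg <- NA_real_
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    pk <- mwi[p]
    if (length(qrs) && p - qrs[length(qrs)] < refractory) {
      i <- i + 1L
      next
    }
    if (pk > thr()) {
      qrs <- c(qrs, p)
      spki <- 0.125 * pk + 0.875 * spki
      if (length(qrs) >= 2) {
        rr_last <- diff(utils::tail(qrs, 9))
        rr_avg <- mean(rr_last)
      }
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back for a missed beat
      if (length(qrs) && !is.na(rr_avg) && p - qrs[length(qrs)] > 1.66 * rr_avg) {
        seg <- cand[cand > qrs[length(qrs)] + refractory & cand <= p]
        if (length(seg)) {
          best <- seg[which.max(mwi[seg])]
          if (mwi[best] > 0.5 * thr()) {
            qrs <- sort(c(qrs, best))
            spki <- 0.25 * mwi[best] + 0.75 * spki
          }
        }
      }
    }
    i <- i + 1L
  }
  if (length(qrs) < 2) stop(sprintf("no R peaks found in record '%s'", ecg$subject_id))
  # refine to the local maximum of the input waveform
  hw <- round(0.075 * fs)
  ref <- vapply(qrs, function(p) {
    lo <- max(1L, p - hw)
    hi <- min(n, p + hw)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  ref <- ref[c(TRUE, diff(ref) >= refractory)]
  rpeak_series(ref, fs, ecg$t0)
}

# -- CGM delay ---------------------------------------------------------------

#' Remove the CGM sensor delay
#'
#' Shifts timestamps 15 min earlier so CGM values line up with blood-glucose
#' time. Applying it twice is an error.
#'
#' @param g a `glucose_series`.
#' @param delay_min sensor delay, minutes.
#' @return the corrected `glucose_series`.
#' @export
correct_cgm_delay <- function(g, delay_min = 15) {
  stopifnot(inherits(g, "glucose_series"))
  if (g$delay_corrected) stop("glucose series is already delay-corrected")
  g$t_min <- g$t_min - delay_min
  g$delay_corrected <- TRUE
  g
}

# -- windowing ---------------------------------------------------------------

#' Segment a record into 2-min windows
#'
#' Windows are `window_s * fs` samples (30,000 at 250 Hz); stride 120 s for
#' model inputs or 60 s for trend analysis. A window's RR series contains the
#' NN intervals whose later beat falls inside the window; windows with fewer
#' than `min_beats` NN intervals are discarded (logged in the `drop_log`
#' attribute).
#'
#' @param ecg an `ecg_record`.
#' @param peaks an `rpeak_series` for the record.
#' @param stride_s stride in seconds (120 or 60).
#' @param window_s window length in seconds.
#' @param min_beats minimum NN intervals to retain a window.
#' @return list of windows (`subject_id`, `window_start`, `nn_ms`,
#'   `beat_times`, `peak_indices`), possibly empty; attribute `drop_log`.
#' @export
segment_windows <- function(ecg, peaks, stride_s = 120, window_s = 120, min_beats = 30) {
  stopifnot(inherits(ecg, "ecg_record"), inherits(peaks, "rpeak_series"))
  dur <- length(ecg$samples) / ecg$fs
  if (dur < window_s) return(structure(list(), drop_log = data.frame()))
  starts <- seq(0, dur - window_s, by = stride_s)
  bt <- peaks$times - ecg$t0
  nn_all <- diff(peaks$times) * 1000
  later <- bt[-1]
  drop <- list()
  out <- list()
  for (s0 in starts) {
    in_w <- later >= s0 & later < s0 + window_s
    pk_in <- bt >= s0 & bt < s0 + window_s
    if (sum(in_w) < min_beats) {
      drop[[length(drop) + 1]] <- data.frame(subject_id = ecg$subject_id,
                                             window_start = s0,
                                             reason = "too_few_beats")
      next
    }
    out[[length(out) + 1]] <- list(
      subject_id = ecg$subject_id,
      window_start = s0,
      nn_ms = nn_all[in_w],
      beat_times = later[in_w],
      peak_indices = peaks$indices[pk_in]
    )
  }
  structure(out, drop_log = if (length(drop)) do.call(rbind, drop) else data.frame())
}

#' Extract fixed-length beats around R peaks
#'
#' Each beat spans 200 samples: 80 before the R peak and 120 from the peak on
#' (0-based samples `[R - 80, R + 120)`). Beats whose span exits the record
#' are dropped, never padded.
#'
#' @param ecg the `ecg_record` the peaks index into.
#' @param peak_indices 1-based R sample indices.
#' @param pre,post samples before/from the R peak.
#' @return numeric matrix, one beat per row (`n_kept x (pre + post)`).
#' @export
extract_beats <- function(ecg, peak_indices, pre = 80, post = 120) {
  n <- length(ecg$samples)
  keep <- peak_indices - pre >= 1 & peak_indices + post - 1 <= n
  idx <- peak_indices[keep]
  m <- matrix(0, nrow = length(idx), ncol = pre + post)
  for (i in seq_along(idx)) {
    m[i, ] <- ecg$samples[(idx[i] - pre):(idx[i] + post - 1)]
  }
  m
}

#' Trim all windows to the dataset-wide minimum beat count
#'
#' `n_min` is the smallest beat count over all retained windows; every
#' window's beat matrix is truncated to its first `n_min` rows, preserving
#' chronological order, so model inputs share one shape.
#'
#' @param windows list of windows carrying `beats` matrices.
#' @return the trimmed window list (attribute `n_min`).
#' @export
fix_beat_count <- function(windows) {
  stopifnot(length(windows) > 0)
  counts <- vapply(windows, function(w) nrow(w$beats), integer(1))
  if (any(counts < 1)) stop("every window must have at least one beat")
  n_min <- min(counts)
  if (n_min < 10) warning(sprintf("minimum beat count is %d (< 10): degenerate dataset", n_min))
  out <- lapply(windows, function(w) {
    w$beats <- w$beats[seq_len(n_min), , drop = FALSE]
    w
  })
  structure(out, n_min = n_min, drop_log = attr(windows, "drop_log"))
}

#' Label windows against the nearest glucose sample
#'
#' Pairs each window with the delay-corrected CGM sample nearest its center
#' time (ties resolved to the earlier sample) and labels it hyperglycemia iff
#' glucose >= 180 mg/dL. Windows with no CGM sample within 10 min of center
#' are dropped and logged.
#'
#' @param windows list of windows (each with `window_start`, seconds).
#' @param g a delay-corrected `glucose_series`.
#' @param window_s window length, s.
#' @param threshold label threshold, mg/dL.
#' @return list of labeled windows with `glucose` and `label` fields;
#'   attribute `drop_log` extended with unmatched windows.
#' @export
label_windows <- function(windows, g, window_s = 120, threshold = 180) {
  stopifnot(inherits(g, "glucose_series"))
  if (!g$delay_corrected) stop("glucose series must be delay-corrected before labeling")
  drop <- attr(windows, "drop_log") %||% data.frame()
  out <- list()
  for (w in windows) {
    center_min <- (w$window_start + window_s / 2) / 60
    d <- abs(g$t_min - center_min)
    j <- which.min(d)   # ties -> earlier sample
    if (d[j] > 10) {
      drop <- rbind(drop, data.frame(subject_id = w$subject_id,
                                     window_start = w$window_start,
                                     reason = "no_cgm_match"))
      next
    }
    w$glucose <- g$values[j]
    w$label <- if (g$values[j] >= threshold) "hyperglycemia" else "euglycemia"
    out[[length(out) + 1]] <- w
  }
  structure(out, drop_log = drop, n_min = attr(windows, "n_min"))
}
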
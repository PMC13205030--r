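# -- trend extraction --------------------------------------------------------

#' Smoothed per-window HRV trend on the 5-min CGM grid
#'
#' Takes the per-window values of one index computed at 1-min stride, smooths
#' them with LOWESS and averages the smoothed values onto the 5-min grid
#' (each grid time collects window centers within +/- 2.5 min).
#'
#' The default smoother span is 0.05 with one iteration: spans much wider
#' than the glucose excursion timescale leave the per-subject correlation
#' test badly miscalibrated under the null (see the methods vignette), while
#' 0.05 preserves both calibration and lag recovery.
#'
#' @param features feature table computed at 1-min stride (>= 20 windows).
#' @param index_name one of [hrv_index_names()].
#' @param frac LOWESS span; `frac = 0` skips smoothing entirely and
#'   aggregates the raw per-window values (the calibrated inference series;
#'   see [best_lag()]).
#' @param iter LOWESS robustness iterations.
#' @param window_s window length, s.
#' @param grid_step grid spacing, min.
#' @return a `trend_series` (fields `t_min`, `values`).
#' @export
hrv_trend <- function(features, index_name = "MeanNN", frac = 0.05, iter = 1,
                      window_s = 120, grid_step = 5) {
  if (!index_name %in% names(features)) stop(sprintf("unknown index '%s'", index_name))
  if (nrow(features) < 20) stop("need at least 20 overlapping windows")
  ctr <- (features$window_start + window_s / 2) / 60
  v <- features[[index_name]]
  ok <- is.finite(v)
  sm <- if (frac > 0) stats::lowess(ctr[ok], v[ok], f = frac, iter = iter)
        else list(x = ctr[ok], y = v[ok])
  grid <- seq(0, max(ctr), by = grid_step)
  vals <- vapply(grid, function(g) {
    sel <- abs(sm$x - g) <= grid_step / 2
    if (any(sel)) mean(sm$y[sel]) else NA_real_
  }, numeric(1))
  keep <- is.finite(vals)
  structure(list(t_min = grid[keep], values = vals[keep]), class = "trend_series")
}

# -- cross-correlation -------------------------------------------------------

# align a trend series and a glucose series onto their common 5-min grid
common_grid <- function(x, y) {
  tx <- round(x$t_min, 6); ty <- round(y$t_min, 6)
  tt <- intersect(tx, ty)
  if (length(tt) < 2) stop("series share fewer than 2 grid points")
  list(x = x$values[match(tt, tx)], y = y$values[match(tt, ty)], t = sort(tt))
}

#' Cross-correlation at one lag
#'
#' Pearson correlation between `x_t` and `y_{t + k}` over the overlapping
#' range of the two series on their common grid (`k` in grid steps). A
#' positive `k` pairs the HRV trend with later glucose samples, so under this
#' package's convention the best `k` recovers a configured positive
#' `lag_steps` (glucose trails HRV).
#'
#' @param x a `trend_series`.
#' @param y a delay-corrected `glucose_series` on the same grid.
#' @param k integer lag in grid steps.
#' @param min_overlap minimum overlapping points.
#' @return the correlation coefficient.
#' @export
cross_correlation <- function(x, y, k, min_overlap = 10) {
  g <- common_grid(x, y)
  n <- length(g$x)
  k <- as.integer(k)
  if (k >= 0) { xi <- seq_len(n - k); yi <- xi + k } else { yi <- seq_len(n + k); xi <- yi - k }
  if (length(xi) < min_overlap) stop("overlap after shift below minimum")
  xv <- g$x[xi]; yv <- g$y[yi]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) stop("zero variance in overlap")
  sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
}

#' Pearson correlation t test
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the two-tailed Student-t
#' critical value with `n - 2` df.
#'
#' @param r correlation.
#' @param n sample size (>= 3).
#' @param alpha two-tailed level.
#' @return list `t`, `t_crit`, `significant`.
#' @export
pearson_t_test <- function(r, n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) stop("|r| = 1 is degenerate")
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  t_crit <- stats::qt(1 - alpha / 2, df = n - 2)
  list(t = t, t_crit = t_crit, significant = abs(t) > t_crit)
}

#' Lag group assignment
#'
#' `lag < -4` is "early" (HRV trails), `-4 <= lag <= 4` "synchronous",
#' `lag > 4` "late".
#'
#' @param lag_steps integer lag.
#' @return character group.
#' @export
assign_group <- function(lag_steps) {
  ifelse(lag_steps < -4, "early", ifelse(lag_steps > 4, "late", "synchronous"))
}

#' Best-lag cross-correlation for one subject
#'
#' Scans `k` in `[-k_max, k_max]` and selects the lag maximizing `|r|`; ties
#' are broken toward the smallest `|k|`, then negative before positive. The
#' significance reported at the selected lag uses the single-correlation t
#' test exactly as published; because the lag was selected by maximizing
#' `|r|`, that test over-rejects under the null and `r_max` should be read as
#' descriptive (the `selection_note` field records this).
#'
#' Smoothing the trend before correlating inflates the test's type-I error
#' (neighbouring grid points share smoothed information), so when an
#' `x_infer` series is supplied — typically the raw aggregation of
#' *non-overlapping* 2-min windows, via `hrv_trend(..., frac = 0)` computed
#' at 120-s stride — the t test is evaluated on `x_infer` at the selected
#' lag, keeping the test calibrated while the smoothed series still drives
#' lag selection.
#'
#' @param x a `trend_series` (smoothed; drives the lag scan).
#' @param y a delay-corrected `glucose_series`.
#' @param subject_id id carried into the result.
#' @param k_max lag scan bound, grid steps.
#' @param min_overlap minimum overlap per lag.
#' @param alpha test level.
#' @param x_infer optional unsmoothed `trend_series` used for the t test.
#' @return a `lag_result`: `subject_id`, `lag_steps`, `r_max`, `n`, `t_stat`,
#'   `t_crit`, `significant`, `group`.
#' @export
best_lag <- function(x, y, subject_id = "?", k_max = 24, min_overlap = 10,
                     alpha = 0.05, x_infer = NULL) {
  ks <- -k_max:k_max
  ks <- ks[order(abs(ks), ks)]   # tie order: smallest |k|, negative first
  best <- NULL
  for (k in ks) {
    r <- tryCatch(cross_correlation(x, y, k, min_overlap), error = function(e) NA_real_)
    if (is.na(r)) next
    if (is.null(best) || abs(r) > abs(best$r)) best <- list(k = k, r = r)
  }
  if (is.null(best)) stop("no valid lag in the scan range")
  xt <- x_infer %||% x
  r_test <- tryCatch(cross_correlation(xt, y, best$k, min_overlap),
                     error = function(e) best$r)
  n <- length(common_grid(xt, y)$x) - abs(best$k)
  tst <- if (abs(r_test) >= 1 - 1e-12) {
    # perfectly correlated pair: the t statistic diverges
    list(t = sign(r_test) * Inf, t_crit = stats::qt(1 - alpha / 2, n - 2),
         significant = TRUE)
  } else {
    pearson_t_test(r_test, n, alpha)
  }
  structure(list(subject_id = subject_id, lag_steps = best$k, r_max = best$r,
                 n = n, t_stat = tst$t, t_crit = tst$t_crit,
                 significant = tst$significant,
                 group = assign_group(best$k),
                 selection_note = "r_max selected over lags; single-lag test is descriptive"),
            class = "lag_result")
}

#' Cohort lag summary table
#'
#' One row per subject (lag, r, t, significance, group) plus the cohort means
#' of lag and r rounded to 2 decimal places (as attributes `mean_lag`,
#' `mean_r`, and a final "Mean" row).
#'
#' @param results list of `lag_result`s, or a data.frame with columns
#'   `lag_steps` and `r`.
#' @return data.frame; attributes `mean_lag`, `mean_r` (NULL when empty).
#' @export
cohort_lag_table <- function(results) {
  if (is.data.frame(results)) {
    df <- data.frame(subject_id = results$subject_id %||% seq_len(nrow(results)),
                     lag_steps = results$lag_steps, r = results$r,
                     t_stat = NA_real_, significant = NA,
                     group = assign_group(results$lag_steps))
  } else {
    df <- do.call(rbind, lapply(results, function(x) {
      data.frame(subject_id = x$subject_id, lag_steps = x$lag_steps, r = x$r_max,
                 t_stat = x$t_stat, significant = x$significant, group = x$group)
    }))
  }
  if (is.null(df) || nrow(df) == 0) {
    return(structure(data.frame(), mean_lag = NULL, mean_r = NULL))
  }
  structure(df,
            mean_lag = round(mean(df$lag_steps), 2),
            mean_r = round(mean(df$r), 2))
}
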
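# Independent brute-force oracles: every index re-derived straight from its
# definition with plain loops, sharing no code with the package internals.

o_meannn <- function(x) sum(x) / length(x)
o_sdnn <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
o_rmssd <- function(x) {
  d <- x[-1] - x[-length(x)]
  sqrt(sum(d^2) / length(d))
}
o_pnn <- function(x, thr) {
  d <- abs(x[-1] - x[-length(x)])
  100 * sum(d > thr) / length(d)
}
o_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
o_sd1 <- function(x) o_rmssd(x) / sqrt(2)
o_sd2 <- function(x) sqrt(max(0, 2 * o_sdnn(x)^2 - o_sd1(x)^2))

o_shanen <- function(x, bins = 10) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  counts <- numeric(bins)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * bins) + 1
    if (b > bins) b <- bins
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

o_fuzzyen <- function(x, m = 2, r = 0.2 * sd(x), n_exp = 2) {
  N <- length(x)
  phi <- function(mm) {
    nv <- N - mm + 1
    tot <- 0; cnt <- 0
    for (i in 1:(nv - 1)) {
      ti <- x[i:(i + mm - 1)]; ti <- ti - mean(ti)
      for (j in (i + 1):nv) {
        tj <- x[j:(j + mm - 1)]; tj <- tj - mean(tj)
        d <- max(abs(ti - tj))
        tot <- tot + exp(-(d^n_exp) / r)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  log(phi(m)) - log(phi(m + 1))
}

o_sampen_counts <- function(x, m = 2, r) {
  N <- length(x); nv <- N - m
  A <- 0; B <- 0
  if (nv < 2) return(c(B = 0, A = 0))
  for (i in 1:(nv - 1)) {
    for (j in (i + 1):nv) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  c(B = B, A = A)
}

o_coarse <- function(x, s, off = 1) {
  n <- floor((length(x) - off + 1) / s)
  out <- numeric(n)
  for (i in 1:n) out[i] <- mean(x[(off + (i - 1) * s):(off + i * s - 1)])
  out
}

o_multiscale <- function(x, m = 2, scales = 1:3, r = 0.2 * sd(x)) {
  mse <- cmse <- rcmse <- rep(NA_real_, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    ents <- rep(NA_real_, s); At <- 0; Bt <- 0
    for (o in 1:s) {
      cnt <- o_sampen_counts(o_coarse(x, s, o), m, r)
      Bt <- Bt + cnt["B"]; At <- At + cnt["A"]
      if (cnt["B"] > 0 && cnt["A"] > 0) ents[o] <- -log(cnt["A"] / cnt["B"])
    }
    mse[si] <- ents[1]
    if (any(!is.na(ents))) cmse[si] <- mean(ents, na.rm = TRUE)
    if (Bt > 0 && At > 0) rcmse[si] <- -log(At / Bt)
  }
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  c(MSEn = mn(mse), CMSEn = mn(cmse), RCMSEn = mn(rcmse))
}

o_cd <- function(x, m = 2) {
  n <- length(x) - m + 1
  d <- numeric(n * (n - 1) / 2)
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    d[k] <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
  }
  d <- d[d > 0]
  qs <- quantile(d, c(0.1, 0.5))
  rs <- exp(seq(log(qs[1]), log(qs[2]), length.out = 8))
  cr <- sapply(rs, function(r) mean(d <= r))
  keep <- cr > 0
  unname(coef(lm(log(cr[keep]) ~ log(rs[keep])))[2])
}

o_hfd <- function(x, kmax = 10) {
  N <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm_ <- numeric(k)
    for (m0 in 1:k) {
      idx <- seq(m0, N, by = k)
      lm_[m0] <- sum(abs(diff(x[idx]))) * (N - 1) / (floor((N - m0) / k) * k) / k
    }
    lk[k] <- mean(lm_)
  }
  unname(-coef(lm(log(lk) ~ log(1:kmax)))[2])
}

o_kfd <- function(x) {
  n <- length(x) - 1
  L <- 0
  for (i in 1:n) L <- L + sqrt(1 + (x[i + 1] - x[i])^2)
  d <- 0
  for (i in seq_along(x)) d <- max(d, sqrt((i - 1)^2 + (x[i] - x[1])^2))
  log10(n) / (log10(n) + log10(d / L))
}

# direct-definition Lomb-Scargle band powers, same grid conventions
o_lsp_bands <- function(bt, nn, oversample = 4) {
  x <- nn - mean(nn)
  n <- length(x)
  span <- max(bt) - min(bt)
  df <- 1 / (oversample * span)
  fhi <- 1000 / (2 * mean(nn))
  freqs <- seq(df, fhi, by = df)
  bands <- c(VLF = 0, LF = 0, HF = 0, VHF = 0)
  for (f in freqs) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * bt)), sum(cos(2 * w * bt))) / (2 * w)
    ct <- cos(w * (bt - tau)); st <- sin(w * (bt - tau))
    p <- 0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
    p <- p * 2 / (n * oversample)
    b <- if (f < 0.04) "VLF" else if (f < 0.15) "LF" else if (f < 0.4) "HF" else "VHF"
    bands[b] <- bands[b] + p
  }
  c(bands["VLF"], bands["LF"], bands["HF"],
    LFHF = unname(if (bands["HF"] > 0) bands["LF"] / bands["HF"] else NA_real_),
    bands["VHF"], TotalPower = sum(bands))
}

o_mobility <- function(x) {
  v <- mean((x - mean(x))^2)
  d <- x[-1] - x[-length(x)]
  sqrt(mean((d - mean(d))^2) / v)
}
o_complexity <- function(x) {
  d <- x[-1] - x[-length(x)]
  o_mobility(d) / o_mobility(x)
}
o_skew <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
o_kurt <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

# full 31-vector oracle in canonical order
oracle_hrv_vector <- function(nn, bt, ecg) {
  c(MeanNN = o_meannn(nn), SDNN = o_sdnn(nn), RMSSD = o_rmssd(nn),
    pNN50 = o_pnn(nn, 50), pNN20 = o_pnn(nn, 20), MedianNN = o_median(nn),
    SD1 = o_sd1(nn), SD2 = o_sd2(nn), SD1SD2 = o_sd1(nn) / o_sd2(nn),
    ShanEn = o_shanen(nn), FuzzyEn = o_fuzzyen(nn), o_multiscale(nn),
    CD = o_cd(nn), HFD = o_hfd(nn), KFD = o_kfd(nn),
    o_lsp_bands(bt, nn),
    RRI_mobility = o_mobility(nn), ECG_mobility = o_mobility(ecg),
    RRI_complexity = o_complexity(nn), ECG_complexity = o_complexity(ecg),
    RRI_skewness = o_skew(nn), ECG_skewness = o_skew(ecg),
    RRI_kurtosis = o_kurt(nn), ECG_kurtosis = o_kurt(ecg))
}
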
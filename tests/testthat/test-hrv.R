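test_that("time-domain indices match hand arithmetic", {
  td <- time_domain(c(800, 820, 800))
  expect_equal(unname(td["RMSSD"]), 20)
  td2 <- time_domain(c(780, 800, 820))
  expect_equal(unname(td2["SDNN"]), 20)
  expect_equal(unname(td2["MeanNN"]), 800)
  expect_equal(unname(td2["MedianNN"]), 800)
  alt <- rep(c(800, 860), 10)
  td3 <- time_domain(alt)
  expect_equal(unname(td3["pNN50"]), 100)
  expect_equal(unname(td3["pNN20"]), 100)
  expect_error(time_domain(800), "2 NN")
})

test_that("Poincare identities hold exactly", {
  for (seed in 1:5) {
    w <- random_rr_window(seed)
    pc <- poincare(w$nn)
    td <- time_domain(w$nn)
    expect_equal(unname(pc["SD1"]), unname(td["RMSSD"]) / sqrt(2), tolerance = 1e-12)
    expect_equal(unname(pc["SD1"]^2 + pc["SD2"]^2), unname(2 * td["SDNN"]^2),
                 tolerance = 1e-9)
  }
  pc0 <- poincare(rep(800, 10))
  expect_equal(unname(pc0["SD1"]), 0)
  expect_equal(unname(pc0["SD2"]), 0)
  expect_true(is.na(pc0["SD1SD2"]))
})

test_that("entropies are zero for constant series and defined for noise", {
  const <- rep(800, 40)
  expect_equal(shannon_entropy(const), 0)
  expect_equal(fuzzy_entropy(const), 0)
  e <- entropy_indices(random_rr_window(3)$nn)
  expect_true(all(is.finite(e[c("ShanEn", "FuzzyEn", "MSEn")])))
  expect_error(entropy_indices(rnorm(10)), "30")
})

test_that("fractal dimensions honour known analytic properties", {
  line <- seq(700, 900, length.out = 100)
  expect_equal(katz_fd(line), 1)
  expect_lt(abs(higuchi_fd(line) - 1), 0.05)
  set.seed(8)
  wn <- rnorm(500)
  h <- higuchi_fd(wn)
  expect_gt(h, 1.5)
  expect_lte(h, 2.05)
  fr <- fractal_indices(rep(800, 40))
  expect_true(all(is.na(fr)))
})

test_that("Lomb-Scargle bands recover planted tones and partition total power", {
  # 0.1 Hz (LF) modulation of the tachogram
  make_rr <- function(f_mod) {
    bt <- cumsum(rep(0.8, 150))
    nn <- 800 + 30 * sin(2 * pi * f_mod * bt)
    list(bt = bt, nn = nn)
  }
  lf <- lsp_bands(make_rr(0.1)$bt, make_rr(0.1)$nn)
  expect_gt(lf["LF"], 10 * lf["HF"])
  hf <- lsp_bands(make_rr(0.25)$bt, make_rr(0.25)$nn)
  expect_gt(hf["HF"], 10 * hf["LF"])
  for (seed in 1:5) {
    w <- random_rr_window(seed)
    b <- lsp_bands(w$bt, w$nn)
    expect_equal(unname(b["VLF"] + b["LF"] + b["HF"] + b["VHF"]),
                 unname(b["TotalPower"]), tolerance = 1e-6)
  }
})

test_that("Hjorth statistics match closed forms for sampled sinusoids", {
  P <- 20
  x <- sin(2 * pi * seq_len(4000) / P)
  hs <- hjorth_stats(x, x)
  expect_equal(unname(hs["RRI_mobility"]), 2 * sin(pi / P), tolerance = 1e-3)
  expect_equal(unname(hs["RRI_complexity"]), 1, tolerance = 1e-3)
  # symmetric two-point series: zero skewness
  expect_equal(unname(hjorth_stats(rep(c(1, -1), 10), rep(c(1, -1), 10))["RRI_skewness"]), 0)
})

test_that("assembled vector has the canonical 31-slot layout with explicit NAs", {
  w <- random_rr_window(5)
  v <- assemble_hrv_vector(w$nn, w$bt, rnorm(1000))
  expect_length(v, 31)
  expect_identical(names(v), hrv_index_names())
  # a constant window forces NA slots but keeps the length
  vc <- assemble_hrv_vector(rep(800, 60), cumsum(rep(0.8, 60)), rnorm(1000))
  expect_length(vc, 31)
  expect_true(any(is.na(vc)))
  # stable ordering across calls
  v2 <- assemble_hrv_vector(w$nn, w$bt, rnorm(1000))
  expect_identical(names(v2), names(v))
})

test_that("normalization applies the mean-NN rule and the z-score rule", {
  w <- fake_windows(12)
  feats <- compute_hrv_features(w)
  st <- subject_stats(feats)
  norm <- normalize_hrv(feats, st)
  # mean-NN rescaling: SDNN 20 at meanNN 800 -> 2.5
  sid <- feats$subject_id[1]
  manual <- feats$SDNN[feats$subject_id == sid] / st[[sid]]$mean_nn * 100
  expect_equal(norm$SDNN[norm$subject_id == sid], manual)
  # z-scored indices have per-subject mean 0 and sd 1
  for (idx in c("MeanNN", "FuzzyEn", "LF", "RRI_skewness")) {
    z <- norm[[idx]][norm$subject_id == sid]
    if (sd(feats[[idx]][feats$subject_id == sid]) > 0) {
      expect_lt(abs(mean(z)), 1e-9)
      expect_equal(sd(z), 1, tolerance = 1e-9)
    }
  }
  expect_error(normalize_hrv(norm, st), "already")
})

test_that("scaling all NN by a constant scales Eq.1 inputs and cancels after Eq.1", {
  w <- random_rr_window(9)
  a <- time_domain(w$nn); pa <- poincare(w$nn)
  b <- time_domain(w$nn * 2); pb <- poincare(w$nn * 2)
  for (k in c("SDNN", "RMSSD")) expect_equal(unname(b[k]), 2 * unname(a[k]))
  for (k in c("SD1", "SD2")) expect_equal(unname(pb[k]), 2 * unname(pa[k]))
  # Eq. 1 normalized values are scale-free
  expect_equal(unname(b["SDNN"] / b["MeanNN"]), unname(a["SDNN"] / a["MeanNN"]))
})

test_that("indices agree with brute-force oracles on seeded windows", {
  # a lighter version of the acceptance sweep: 5 windows, all 31 indices
  for (seed in 101:105) {
    w <- random_rr_window(seed, n = 110)
    set.seed(seed + 1000)
    ecg <- rnorm(2000, sd = 0.3)
    got <- assemble_hrv_vector(w$nn, w$bt, ecg)
    want <- oracle_hrv_vector(w$nn, w$bt, ecg)
    ent <- c("ShanEn", "FuzzyEn", "MSEn", "CMSEn", "RCMSEn")
    for (k in hrv_index_names()) {
      tol <- if (k %in% ent) 1e-4 else 1e-6
      expect_equal(unname(got[k]), unname(want[k]), tolerance = tol,
                   label = paste("index", k, "seed", seed))
    }
  }
})
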
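# glycohrv

Noninvasive detection of acute hyperglycemia from single-lead wearable ECG.

During an oral glucose tolerance test (OGTT), the glucose excursion perturbs
autonomic tone and cardiac conduction: mean heart period (NN) shortens,
beat-to-beat variability (HRV) collapses, and PR/QT intervals lengthen
slightly. `glycohrv` is an end-to-end, fully testable R implementation of an
analysis built on that physiology:

* **Synthetic OGTT cohorts** — gamma-shaped glucose excursions
  `G(t) = G0 + A·u·e^(1−u)`, RR dynamics coupled to lagged normalized
  glucose, sum-of-Gaussians P-QRS-T beat morphology at 250 Hz with mild
  glucose-dependent PR/QT modulation, and a CGM sensor model (15-min delay,
  5-min grid, 3 mg/dL noise). Everything is seeded and regenerates
  byte-identically, so the whole pipeline is testable with no data download.
* **Preprocessing** — stand-in signal-quality screen, 1–40 Hz zero-phase
  Butterworth filtering, Pan–Tompkins R-peak detection (with an override
  hook standing in for manual correction), 2-min windowing, 200-sample beat
  extraction (80 pre / 120 post samples), glucose labeling at the
  180 mg/dL threshold.
* **31 HRV indices** per window — time-domain, Poincaré, entropy
  (Shannon/fuzzy/multiscale), fractal (correlation dimension,
  Higuchi, Katz), Lomb–Scargle band powers of the uneven tachogram, and
  Hjorth/moment statistics — with subject-wise normalization
  (`raw/meanNN·100` for dispersion indices, z-scores for the rest).
* **HRV–glucose lag analysis** — LOWESS-smoothed MeanNN trend
  cross-correlated with the CGM over lags ±24 five-min steps
  (`r_xy(k) = corr(x_t, y_{t+k})`), per-subject best lag, Pearson
  significance `t = r√(n−2)/√(1−r²)`, and grouping into early /
  synchronous / late responders.
* **Dual-input detector** — a TimeDistributed 1-D conv encoder per beat
  (32 filters, kernels 5 and 3, batch norm, max-pool, dropout) + BiLSTM(64)
  + dense ECG embedding, fused with a dense HRV branch through
  64→32→16→softmax, trained with focal loss under personalized
  temporal-split five-fold cross-validation. The network, its backprop and
  Adam are implemented in this package (R + a few Rcpp kernels); all
  gradients are finite-difference-verified in the test suite.
* **Interpretability** — gradient saliency of the hyperglycemia logit over
  the 200-sample beat frame, and one-at-a-time HRV feature masking.

See `vignettes/methods.Rmd` for the models, parameter choices, numerical
conventions, and what the synthetic world does and does not establish.

## Worked example

```r
library(glycohrv)

cc <- cohort_config(n_subjects = 4, fraction_crossing_threshold = 0.75,
                    lag_distribution = data.frame(lag_steps = c(0L, 2L),
                                                  prob = c(0.6, 0.4)),
                    master_seed = 42, coupling_strength = 0.9)
res <- run_pipeline(cc, max_beats = 8,
                    spec_args = list(max_epochs = 6, es_patience = 3), seed = 1)

res$lag_table
#>   subject_id lag_steps      r t_stat significant       group
#> 1        S01         0 -0.998  -85.9        TRUE synchronous
#> 2        S02         2 -0.979  -26.0        TRUE synchronous
#> 3        S03         2 -0.996  -66.1        TRUE synchronous
#> 4        S04         2 -0.996  -66.0        TRUE synchronous

res$report$folds
#>   fold accuracy precision sensitivity specificity    f1    auc
#> 1    1    0.886     1.000       0.467       1.000 0.636 0.9842
#> 2    2    0.899     0.000       0.000       0.899 0.000     NA
#> 3    3    0.690     0.588       0.714       0.674 0.645 0.8372
#> 4    4    0.732     0.657       0.767       0.707 0.708 0.8228
#> 5    5    0.746     0.769       0.769       0.719 0.769 0.8718
#> 6  AVG    0.791     0.603       0.543       0.800 0.552 0.8790
#> 7  STD    0.095     0.371       0.328       0.142 0.313 0.0731

head(res$importance)
#>             index importance
#> 3           RMSSD     0.0470
#> 7             SD1     0.0394
#> 27 ECG_complexity     0.0244
#> 9          SD1SD2     0.0236
#> 15             CD     0.0118
#> 29   ECG_skewness     0.0107
```

Reading the output: every estimated lag matches the configured one (0 or +2
five-min steps; r is negative because mean NN falls as glucose rises), so
all four subjects land in the synchronous group and reach the detector.
Fold 2 of this tiny 4-subject example happens to draw no hyperglycemic
windows into its test set — its sensitivity is 0 and AUC undefined — a
faithful illustration of how temporal-split fold composition drives
fold-to-fold variability; the acceptance-scale 10-subject cohort averages
AUC ≥ 0.85. The masking importances rank short-term-variability indices
(RMSSD, SD1) on top, matching the physiology the generator plants.

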
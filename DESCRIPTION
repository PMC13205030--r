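Package: glycohrv
Title: Noninvasive Acute-Hyperglycemia Detection from Wearable ECG and Heart Rate Variability
Version: 0.1.0
Authors@R: person("glycohrv", "maintainers", email = "maintainers@glycohrv.dev", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for detecting acute
    hyperglycemia (glucose >= 180 mg/dL) from single-lead ECG during an oral
    glucose tolerance test. Provides a seeded synthetic OGTT cohort generator
    (glucose excursion, lag-coupled RR dynamics, sum-of-Gaussians ECG morphology,
    CGM sensor model), ECG preprocessing (band-pass filtering, Pan-Tompkins R-peak
    detection, quality screening, 2-min windowing and beat segmentation), 31
    time/frequency/nonlinear HRV indices with subject-wise normalization,
    HRV-glucose cross-correlation lag estimation and subject stratification,
    personalized temporal-split five-fold cross-validation, a dual-input beat
    morphology + HRV neural classifier trained with focal loss, and
    gradient-saliency / feature-masking interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
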
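Package: betamod
Title: Movement-Related Beta ERD/ERS Quantification and Fatigue Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying movement-related beta-band
    (13.5-25 Hz) event-related desynchronization (ERD) and synchronization
    (ERS) from epoched scalp EEG: spherical-spline current source density,
    complex Morlet time-frequency decomposition, whole-trial
    subtract-and-divide baseline normalization, data-driven personalized
    region-of-interest selection, and per-trial peak ERD/ERS, latency and
    modulation-depth extraction. Companion tools cover the surrounding
    clinical-neurophysiology workflow: EMG envelope and onset metrics,
    nonparametric group statistics with bootstrap confidence intervals,
    bias-corrected bootstrap mediation, and an elastic-net logistic
    classifier of fatigue status fitted under repeated stratified nested
    cross-validation with stability selection and a descriptive ridge
    refit. A seeded synthetic-data generator emulates the cued pinch-force
    study design (cue-locked beta dynamics over frontal and sensorimotor
    scalp, 1/f background EEG, EMG bursts, and a correlated multimodal
    feature table) so every stage can be exercised and validated end to
    end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
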
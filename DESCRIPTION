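Package: osascreen
Title: Dual-Channel Oximetry and Airflow Screening for Obstructive Sleep
    Apnoea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the apnoea-hypopnoea index (AHI) from overnight
    pulse-oximetry (SpO2) and nasal-prong-pressure airflow recordings.
    Implements the full screening pipeline: channel-specific signal
    cleaning, a 38-feature parameterisation (time-domain moments,
    band-restricted spectral measures, sample entropy, central tendency
    measure, Lempel-Ziv complexity, and conventional oximetric and
    respiratory indices), bootstrap-stabilised fast correlation-based
    filter (FCBF) feature selection, support-vector regression of the
    AHI with leave-one-out model selection by intraclass correlation,
    and an agreement/diagnostic evaluation layer (ICC, Bland-Altman,
    Cohen's kappa, likelihood ratios, ROC analysis with bootstrap
    confidence intervals).  A synthetic polysomnography simulator with
    scripted respiratory events and known ground-truth AHI makes every
    stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
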
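Package: predstab
Title: Geographic and Temporal Stability of Clinical Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies between-hospital (geographic) and between-period
    (temporal) heterogeneity in the baseline risk and predictor effects of a
    clinical prediction model, using a suite of nine random-effects logistic
    regression models fitted by maximum marginal likelihood. Provides
    variance-component likelihood-ratio tests, the median odds ratio, central
    95% ranges of hospital-specific probabilities and odds ratios, a clustered
    two-period synthetic cohort generator emulating the structure of the
    EFFECT heart-failure registry, and a command-line driver producing JSON
    and TSV reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
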
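Package: fnast8
Title: Derivation and Validation of a Simplified 8-Item Finnegan Neonatal
    Abstinence Score
Version: 0.1.0
Authors@R:
    person("Alex", "Duval", email = "alex.duval@example.org",
           role = c("aut", "cre"))
Description: Tools to derive and evaluate a simplified 8-item version of the
    21-item Finnegan Neonatal Abstinence Scoring Tool (FNAST). Provides the
    full graded item catalogue with integer weights, dichotomization of graded
    items into binary signs, original and simplified score computation,
    site-specific consecutive-score treatment-initiation rules and analysis
    point extraction; cross-cohort heterogeneity screening (Pearson chi-square
    homogeneity tests, endorsement concordance statistics, a percentage-point
    heterogeneity filter); a self-contained iteratively reweighted least
    squares logistic regression with forward stepwise item selection forced on
    cohort; threshold calibration of the simplified scale against the original
    category cutoffs by linear-weighted Cohen's kappa; external validation on
    an independent cohort; and a calibrated synthetic multi-cohort generator
    of longitudinal assessment data so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
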
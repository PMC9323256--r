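Package: pathagree
Title: Multi-Rater Diagnostic Agreement Analysis for Veterinary Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing multi-rater diagnostic agreement
    studies of categorical histopathology diagnoses, built around a four-pathologist
    canine and feline urinary bladder reading design. Provides Fleiss kappa with
    per-category detail and significance, Cohen kappa, bootstrap confidence
    intervals, concurrence with a reference diagnosis (exact confidence limits,
    one-vs-rest sensitivity and specificity, the 'other'-removal rule), a
    probability-based multinomial-logistic predictive tool with delta-method
    probability confidence intervals and exhaustive per-species lookup tables,
    chained-equation polytomous imputation of missing ratings, a kappa-based
    sample-size calculator, and a seeded synthetic-study generator with a
    deterministic fixture matching published marginal counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
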
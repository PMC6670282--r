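Package: oaknet
Title: Semihandcrafted Bayesian Networks for Knee Osteoarthritis Prescreening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network toolkit for prescreening knee
    osteoarthritis from low-cost physical-fitness tests and basic subject
    characteristics. Provides exact inference (variable elimination with an
    enumeration oracle), EM parameter learning under missing data, and a
    constrained hill-climbing structure search scored by cross-validated
    classification accuracy that refines a handcrafted three-level
    (background / disease / predictor) base structure into a semihandcrafted
    network. Includes the full preprocessing pipeline (BMI and waist-to-hip
    ratio derivation, missingness filtering, mean imputation, SMOTE class
    rebalancing, one-dimensional k-means discretization), an evaluation
    protocol with stratified cross-validation and prevalence-adjusted
    predictive values, and a synthetic cohort generator that emulates the
    published cohort summaries so the whole pipeline is testable without
    access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
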
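Package: rsmopt
Title: Response-Surface Modeling and Constrained Dose Nomination for
    Multi-Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits interpretable quadratic phenotypic response surfaces to
    multi-agent dose-response data (cell viability, zebrafish hepatic
    macrophage infiltration ratios), runs a prespecified model-adequacy and
    robustness suite (Shapiro-Wilk, Breusch-Pagan, Durbin-Watson, variance
    inflation factors, K-fold cross-validation, nonparametric bootstrap),
    and nominates candidate dose combinations by constrained multi-objective
    optimization strictly within the experimentally tested dose bounds.
    Includes seeded synthetic-data generators emulating replicated plate
    experiments and zebrafish cohorts, a brute-force grid oracle for
    optimizer verification, and efficiency-corrected delta-delta-Ct
    utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
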
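Package: synthaml
Title: Generation and Evaluation of Synthetic AML Clinical-Trial Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for generating synthetic acute myeloid leukemia (AML)
    clinical-trial cohorts from mixed-type patient tables with censored
    time-to-event endpoints and explicit missing states, and for evaluating
    synthetic cohorts against an original cohort. Includes a Gaussian-copula
    generator with empirical marginals that models event-free survival
    indirectly through the difference to overall survival; normalized
    fidelity scores (regularized support coverage, basic statistical
    measure, log-transformed correlation score); survival-fidelity scores
    (Kaplan-Meier divergence, optimism, short-sightedness); a Hamming
    distance privacy-leakage assessment on binned records; and cohort
    comparison tables with univariable risk-marker concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
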
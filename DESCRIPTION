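Package: dtsurv
Title: Discrete-Time Survival Modelling with Small Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete-time survival analysis designed for training by
    mini-batch stochastic gradient descent. Follow-up time is partitioned
    into left-closed, right-open intervals; each individual's (time, event)
    pair is encoded as a pair of binary target vectors with half-interval
    censoring credit, and a network head (either a fully flexible
    per-interval head or a proportional-hazards head) predicts conditional
    survival probabilities per interval. The negative log likelihood of the
    discrete-time model serves as the loss, so the loss of a mini-batch
    depends only on the individuals in it. Includes evaluation tools
    (Kaplan-Meier curves, Harrell's concordance index, the
    inverse-probability-of-censoring-weighted Brier score, calibration
    tables), cohort simulators for validation experiments, tabular input
    and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
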
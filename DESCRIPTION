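Package: driftrar
Title: Response-Adaptive Randomisation Designs Robust to Time Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference machinery for response-adaptive
    randomised clinical trials with binary outcomes when the outcome
    distribution drifts over time.  Implements block-randomised allocation
    rules (complete randomisation, tuned Thompson sampling, the Rosenberger
    optimal allocation via a doubly-adaptive biased coin design, and the
    forward-looking Gittins index rule with and without control-arm
    protection), Gittins index computation for Bernoulli bandits, a
    Monte-Carlo randomisation test, simulation-calibrated exact tests,
    Firth-penalised logistic regression, and an operating-characteristics
    engine reporting type I error, power, and patient-benefit measures
    (expected number of successes, proportion on the best arm) under
    configurable time-trend and patient-drift scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
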
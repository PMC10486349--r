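Package: mcisim
Title: Simulation and Analysis of a Touchscreen Multiple-Choice Task for
    Captive Macaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An executable model of a cage-mounted touchscreen
    multiple-choice interface (MCI) in which macaques freely choose, trial
    by trial, between a static reach task, a dynamic (bouncing-target)
    reach task, and an unrewarded picture-viewing task. Provides the task
    engine (button layouts, target kinematics with specular reflection,
    touch classification, trial and session state machines), a synthetic
    behavioral agent with known ground-truth parameters (task utilities,
    position biases, within-session engagement decay, speed- and
    size-dependent touch accuracy), and the three analysis stages used to
    characterize such data: within- and across-session engagement
    (normalized trial-time medians, one-sample shift test, partial
    correlations), a hierarchical Bayesian categorical (multinomial-logit)
    mixed model of task preference fitted by an exact Polya-Gamma Gibbs
    sampler, and chance-level-corrected hit-rate psychometrics with
    per-animal speed correlations under Bonferroni control.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
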
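Package: trialhist
Title: Trial-History Analyses of Odor-Cued Spatial Choice Behavior and
    Neural Activity
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing how recent trial history shapes choice
    behavior and single-neuron activity in two-alternative odor-cued
    spatial choice tasks. Provides history-dependent logistic choice
    models with cross-validated model comparison, an ROC-based neural
    preference index with Monte Carlo permutation tests, sliding-window
    encoding regression of spike rates on choice and outcome, a
    trial-by-trial linkage statistic between pre-stimulus firing and
    upcoming choice on ambiguous trials, and contrasts for reversible
    pharmacological inactivation sessions. A synthetic-session generator
    with known ground truth (history-dependent Bernoulli choices,
    inhomogeneous Poisson spike trains) makes every analysis stage
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
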
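Package: fireflynav
Title: Simulation and Analysis of Closed-Loop Optic-Flow Navigation ("Firefly") Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates steering agents performing a landmark-free visual
    navigation task in which a briefly cued target must be reached using only
    optic-flow self-motion cues, under joystick-gain changes, transient
    velocity perturbations, ground-element density changes and limited
    optic-flow duration. Agents span a continuum from pure dead reckoning
    (efference-copy integration) to full sensory integration via a single
    mixing weight. Provides the accompanying analysis suite: shuffle-null ROC
    curves and AUC for continuous endpoint responses, perturbation and gain
    compensation indices, dynamic perturbation-response profiles,
    no-intercept multiplicative-bias regression with bootstrap intervals, and
    the log-space travel-time regression that separates path from time
    integration. Includes an experiment runner producing CSV tables and JSON
    reports from synthetic or imported sessions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
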
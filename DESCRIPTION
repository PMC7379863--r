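Package: effortframe
Title: Effort-Based Decision Making Under Gain and Loss Framing
Version: 0.1.0
Authors@R:
    person("Sandbox", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for effort-based decision-making
    experiments that contrast gain- and loss-framed incentives. Provides
    adaptive (bisection) staircase titration of effort indifference points
    with an endowment pegging rule for loss framing, maximum-likelihood
    fitting and BIC comparison of five effort-discounting families
    (hyperbolic, exponential, linear, quadratic, sigmoid), area-under-the-
    discounting-curve summaries, scoring of motivated vigilance sessions
    (response speed, criterion-relative accuracy, time-on-task slopes),
    tonic pupillometry preprocessing and pre-stimulus extraction, signal-
    detection scoring of incentivized N-back sessions, repeated-measures
    statistics, and a synthetic-agent generator so every stage is testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
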
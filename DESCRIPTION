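Package: jerkpref
Title: Jerk-Controlled Grasp Kinematics and Paired-Comparison Preference
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying perceptual affinity for artificial-agent
    kinematics as a function of movement smoothness.  Synthesizes
    minimum-jerk joint-angle trajectories and jerk-controlled variants
    obtained by adding endpoint-constrained, temporally smooth Gaussian
    noise; computes the average-absolute-jerk smoothness statistic with
    zero-phase low-pass filtering and automatic movement segmentation;
    builds balanced two-alternative forced-choice comparison schedules and
    simulates observers; estimates Bradley-Terry preference strengths by
    maximum likelihood; and compares piecewise linear, flattened and
    reversed jerk-preference models by marginal likelihoods and Bayes
    factors.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
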
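Package: gazeperim
Title: Continuous Gaze-Tracking Perimetry by Spatio-Temporal Integration
    and Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Perimetry", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of continuous gaze-tracking perimetry.
    Generates pseudo-random-walk tracking stimuli, applies gaze-contingent
    visual field defects (central, peripheral, hemifield) to a simulated
    observer, and reconstructs visual field maps from the eye/stimulus time
    series by two complementary routes: threshold-free cluster enhancement
    (TFCE) of positional deviations with normative-percentile thresholding,
    and a two-stream bidirectional GRU network with point-wise and
    shape-classification heads. Includes retinotopic back-projection onto a
    1-degree grid, coverage-corrected mean deviation, 2D Spearman map
    accuracy, participant-aware fivefold cross-validation with percentile
    threshold optimization, false-positive/false-negative error maps, and a
    miscalibration-robustness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
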
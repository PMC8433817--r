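Package: gaitphase
Title: Gait-Phase Event Detection from Ankle-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects foot-off, mid-swing and foot-contact timepoints in walking
    recordings from bilateral ankle inertial measurement units sampled at 100 Hz.
    Implements orientation-invariant magnitude features (angular-velocity,
    free-acceleration and bilateral direction-cosine magnitudes), physical-range
    cleaning and Gaussian smoothing, deterministic peak-based phase labeling with
    step-type classification and turning exclusion, center-labeled sliding-window
    construction, per-phase stacked recurrent (LSTM) sequence models trained with
    Adam on binary cross-entropy, and probability-trace event calling with local
    refinement on the raw signal. Includes a synthetic bilateral gait-signal
    simulator with ground-truth events so the full pipeline can be exercised and
    validated without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
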
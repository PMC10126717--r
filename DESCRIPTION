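Package: rpnidecode
Title: Longitudinal Intramuscular EMG Decoding for Prosthetic Grip Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for longitudinal intramuscular
    electromyography (EMG) recorded from regenerative peripheral nerve
    interfaces (RPNIs) and residual forearm muscles. Generates synthetic
    multichannel EMG with configurable activation patterns and
    session-to-session amplitude drift, extracts mean-absolute-value (MAV)
    features in 50 ms bins, trains a hidden Markov model with Naive Bayes
    emissions (HMM-NB) alongside single-state Naive Bayes and linear
    discriminant baselines, simulates a real-time posture-matching virtual
    task with transition-error and latency metrics, implements a
    grip-selection filter with proportional velocity ramp for physical
    prosthesis control, and provides session-level statistics: signal-to-noise
    ratio tracking, linear trend tests, arm-position comparisons, channel
    ablation, and 2D ICA-PCA feature-space visualization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite,
    tools,
    utils
Suggests:
    MASS,
    cluster,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
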
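Package: imnet
Title: Inverse Muscle Modeling of EMG Envelopes with NARX Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates muscle-excitation (surface-EMG envelope) time series
    from joint-level biomechanical signals with a NARX recurrent neural
    network, inverting the usual muscle-model direction. Provides the full
    data-preparation pipeline for a planar shoulder task: zero-phase
    kinematic filtering and differentiation, planar two-link inverse
    dynamics, a muscle torque generator model and its algebraic inversion to
    activation torque, and a seven-step surface-EMG envelope filter chain.
    Training uses Levenberg-Marquardt with adaptive damping and
    validation-patience early stopping; model selection includes a
    configuration grid search, subject-wise k-fold cross-validation,
    per-channel estimability ranking, and sequential backward input
    selection. A synthetic multi-subject cohort generator supports testing
    and planted-truth recovery studies without motion-capture or EMG
    hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
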
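Package: voicetype
Title: Voice Type Discrimination from Neck-Surface Vibration Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discriminating modal, breathy and pressed phonation
    from neck-surface accelerometer vibration signals of sustained vowels.
    Provides a synthetic-signal generator with controllable harmonic
    envelopes, cycle-period jitter, cycle-amplitude shimmer and broadband
    noise; voice activity detection based on short-time energy and
    zero-crossing rate; extraction of a seven-dimensional feature vector
    (harmonic quotients H1-H4, spectral entropy, relative jitter and
    shimmer); auditory-perceptual panel screening statistics (Fleiss'
    kappa, two-way random intraclass correlation, pure-sample filtering);
    and a five-classifier evaluation harness with leave-one-feature-out
    ablation, per-type accuracy, TPR/FPR/AUC and chi-square comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
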
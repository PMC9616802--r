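Package: wmtheta
Title: Frontal Theta, Working-Memory Decoding and Coherence Analysis for Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of epoched multichannel EEG from
    working-memory experiments: time-resolved spectral power with a
    variable-cycle Hanning decomposition, cluster-based permutation
    inference over channel-frequency(-time) bins, cross-validated linear
    discriminant decoding of stimulus category (timecourse, temporal
    generalization and channel searchlight), seed-based magnitude-squared
    coherence with trial-count-matched subsampling, and a per-trial theta
    peak-frequency statistic with IRASA 1/f control. Includes a synthetic
    EEG session generator (1/f background, load-dependent fronto-medial
    theta oscillators, posterior category patterns, seed-target band
    coupling) with complete ground-truth manifests, so every stage of the
    pipeline can be validated against known effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
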
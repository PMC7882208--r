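Package: aecnet
Title: Amplitude-Envelope Connectivity Networks for Task MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of band-limited amplitude-envelope
    connectivity in source-space magnetoencephalography (MEG). Provides a
    synthetic generator for two-group, multi-trial oscillatory datasets with
    known envelope-coupling structure and zero-lag leakage; epoching with
    amplitude and rigid-body head-motion trial rejection; linearly constrained
    minimum variance (LCMV) beamforming with trace-scaled regularization and
    dominant-orientation projection; symmetric (leakage-correcting)
    orthogonalization, Hilbert-envelope correlation matrices per frequency
    band and time window with fractional-change baselining; the Network-Based
    Statistic with permutation family-wise error control; and node-strength
    brain-behaviour modelling with false-discovery-rate correction.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
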
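Package: stridecost
Title: Stride-to-Stride Variability and the Metabolic Cost of Walking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how stride-to-stride gait variability
    inflates estimates of walking metabolic cost. Generates synthetic
    multi-stride treadmill-style gait trials with controllable variability,
    implements the standard gait data-preparation chain (zero-phase
    Butterworth filtering, heel-strike detection, stride segmentation and
    time normalization, centre-of-pressure swing repair, ensemble-averaged
    gait patterns), computes joint moments by planar inverse dynamics on a
    reduced link-segment model, evaluates a torque-squared effort cost and
    an Umberger-family muscle metabolic cost driven by static-optimization
    muscle states, and compares three cost-averaging methods (single
    stride, averaged gait pattern, mean of per-stride costs). Also includes
    a feedback-controlled inverted-pendulum walker with sensory and motor
    noise for studying how noise raises mean stride cost and its
    dispersion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
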
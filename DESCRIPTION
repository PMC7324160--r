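Package: isnfit
Title: Inference and Analysis of Inhibition-Stabilized Cortical Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling and inferring inhibition-stabilized network (ISN)
    operation in cortical circuits from optogenetic dose-response experiments.
    Implements two- and three-population excitatory/inhibitory firing-rate models
    with rectified-linear or softplus transfer functions, pharmacological blocker
    transforms, fixed-point and linear stability analysis (including the maximal
    stable ratio of inhibitory to excitatory time constants), multi-restart
    bounded nonlinear least-squares inference of network parameters from
    three-phase dose-response curves with bootstrap uncertainty, and the
    unit-level analysis chain used in such experiments: excitatory/inhibitory
    classification (pharmacology, high-power response, waveform width),
    piecewise-linear laser-intensity normalization, initial-slope statistics,
    detection of the brief inhibitory transient that precedes paradoxical
    suppression, and model-based current decomposition. A synthetic-data
    generator emulating the experimental design (three pharmacological phases,
    Poisson trial noise, mixed excitatory/inhibitory unit populations) makes the
    whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
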
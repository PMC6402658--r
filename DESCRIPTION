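Package: isoresponse
Title: Identification of Two-Layer Dendritic Subunit Models from Iso-Response Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying cascade ("two-layer") models of dendritic
    integration from iso-response curves, the level sets of a neuron's
    two-input response surface. Provides forward simulation of point-neuron,
    feedforward two-layer and feedback-extended two-layer subunit models,
    bicubic-spline response surfaces with level-set extraction, reconstruction
    of the per-branch subunit non-linearities from two training curves (up to
    an affine gauge) via a stairway construction or a monotone basis-function
    expansion, prediction and validation on a third test curve, brute-force
    identification of additive and multiplicative output feedback, a
    gradient-angle test of subunit independence, and a synthetic benchmark
    suite of ground-truth models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
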
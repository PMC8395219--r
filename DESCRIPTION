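Package: smdyn
Title: Single-Molecule Dynamics of Membrane Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of single-molecule TIRF time-lapse imaging of membrane
    proteins such as TRPV ion channels: switching-diffusion trajectory
    simulation with known ground truth, spot detection and nearest-neighbour
    tracking, variational-Bayes hidden Markov model clustering of diffusion
    states with evidence-based model selection, mean-squared-displacement and
    confined-diffusion fitting, oligomer-size decomposition of single-molecule
    intensity histograms against a monomeric calibration standard, two-colour
    colocalization kinetics (colocalized fractions, on-rate constants, on-time
    survival), and Hill-equation dose-response and saturation-binding fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    Matrix,
    MASS,
    survival,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
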
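Package: SFDIdepth
Title: Subsurface Fluorescence Depth Quantification with Spatial Frequency
    Domain Imaging and Deep Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, processing and learning pipeline for deep
    learning-enabled spatial frequency domain imaging (SFDI) of buried
    fluorescent tumors. Generates composite-spherical-harmonic tumor
    scenes, propagates patterned excitation light and fluorescence
    emission with a finite-difference diffusion model, recovers
    absorption and reduced-scattering maps by two-frequency lookup-table
    inversion, and trains dual-branch convolutional regressors (a Siamese
    ResNet and an attention U-Net) that predict per-pixel margin distance
    and fluorophore concentration, together with the evaluation metrics
    used for surgical margin assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
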
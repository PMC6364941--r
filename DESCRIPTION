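Package: nmrsigex
Title: Metabolic Signal Extraction from 1D 1H-NMR Spectra by Binning and
    Template Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two routes from 1D proton-NMR blood-plasma
    spectra to classifier-ready features: integration of predefined spectral
    regions (binning) and two-component template deconvolution in which
    metabolite multiplet templates with non-negative coefficients model the
    metabolic signal and a wavelet-regularized residual captures uncatalogued
    broad resonances such as lipids. Includes a synthetic plasma-spectrum
    generator (Lorentzian multiplets with J-coupling, broad lipid humps,
    water and TSP signals, baseline drift and shift jitter), a preprocessing
    chain (apodization, zero-filling, Fourier transformation, phasing,
    asymmetric-least-squares baseline correction, TSP referencing, warping
    alignment, normalization), moderated-t feature ranking, and a repeated
    stratified k-fold cross-validation harness with a pluggable classifier
    contract (elastic net reference implementation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    Matrix,
    pracma,
    limma,
    glmnet,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
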
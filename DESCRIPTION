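Package: multimsi
Title: Correlative Multimodal Mass Spectrometry Imaging: Registration,
    Multiblock Chemometrics and Image Fusion
Version: 0.1.0
Authors@R: person("multimsi", "developers", role = c("aut", "cre"),
    email = "multimsi@example.org")
Description: Tools for correlative chemical imaging of tissue sections by
    multimodal mass spectrometry imaging (MSI) and hyperspectral fluorescence
    microscopy. Reads and writes imzML, applies spectral preprocessing
    (baseline correction, RMS normalization, peak-region extraction), aligns
    modalities at single-pixel precision with an intensity-based
    1+1-evolutionary optimizer under a Mattes mutual-information objective,
    evaluates alignments with MSE, SSIM, Jaccard and mutual-information
    metrics, decomposes the registered multimodal pixel matrix into globally
    joint, locally joint and unique variation with a multiblock OnPLS model,
    ranks MSI variables by OPLS variable importance in projection (VIP), and
    predicts ion distributions at microscopy resolution by PLS-based
    data-driven image fusion. Includes a synthetic phantom generator with
    plaque-like focal features and known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
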
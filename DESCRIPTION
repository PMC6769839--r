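Package: hsimargin
Title: Hyperspectral Tumor-Margin Detection with Ensemble LDA and Patch CNNs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for delineating squamous-cell-carcinoma margins
    in hyperspectral images of excised tissue specimens. Provides flat-field
    calibration of raw hypercubes against dark-current and white-reference
    frames, an ENVI raster reader/writer, synthetic tissue-phantom generation
    with class-separated reflectance spectra, distance-to-margin geometry with
    millimeter-increment evaluation masks, an intra-patient bagged
    linear-discriminant ensemble, an inter-patient patch-based convolutional
    classifier with overlap-averaged heat-map reconstruction, ROC-based
    evaluation at validation-derived operating points, paired one-tailed
    modality comparisons, and grad-CAM spectral saliency profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
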
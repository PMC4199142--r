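Package: fibriquant
Title: Morphometry of Fibrillin Microfibrils and Quantitative Aortic Tissue
    Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of vascular extracellular-matrix imaging
    data. Provides atomic force microscopy (AFM) height-image morphometry of
    beaded fibrillin microfibrils (scanline flattening, artifact masking, bead
    detection with sub-pixel centroids, chain linking, periodicity and length
    measurement), Lorentzian modelling of periodicity histograms with modality
    selection, nonparametric group comparisons, and tissue-section
    quantification (stain area fractions, cubic-spline wall straightening,
    medial thickness, regional gelatinase intensity, and acoustic wave-speed
    statistics with the longitudinal wave-speed/Young's-modulus conversion).
    A synthetic-data generator renders beaded-chain height images and layered
    tissue sections with full ground truth so every stage of the pipeline can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
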
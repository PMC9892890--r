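Package: holocount
Title: Staining-Free Tumor-Cell Enumeration from In-Line Holographic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for label-free enumeration of rare tumor cells
    flowing through a sheathed microfluidic channel, imaged by in-line digital
    holographic microscopy. Provides a physics-based hologram simulator with
    ground-truth cell tracks, object-free background estimation and subtraction,
    angular-spectrum volume reconstruction, 3D cell localization with
    plane-of-best-focus extraction, multiple-count removal across consecutive
    frames, a shallow convolutional network (s-Net) classifier for 36x36
    in-focus cell images, decision-threshold gating with ROC-based threshold
    selection, and per-mL concentration reporting with a limit of detection
    computed from negative-control trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
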
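Package: sandseg
Title: Semi-Supervised Segmentation of Active Neurons in Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments active neurons from motion-corrected two-photon
    calcium-imaging videos using only a handful of labeled frames. Implements
    the SAND approach: matched-filter SNR preprocessing, an ensemble of three
    shallow U-Nets that generates soft pseudolabels for unlabeled frames, a
    staged semi-supervised training schedule (supervised ensemble training,
    pseudolabel training with binary cross-entropy, fine-tuning), a
    four-hyperparameter postprocessing chain (probability thresholding,
    connected-component extraction, cross-frame ROI merging, consecutive-frame
    filtering), and Few Label Hyperparameter Optimization (FLHO) which
    estimates all four postprocessing hyperparameters from the labeled frames
    alone. Includes a seeded synthetic-scene generator with known ground
    truth, and evaluation utilities (mask matching, recall/precision/F1,
    neuron peak SNR, convex-hull mask quality).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    pracma
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
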
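Package: wsidetect
Title: Patch-Based Convolutional Detection of Invasive Carcinoma in
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects invasive breast-cancer regions on digitized whole-slide
    images with a patch-based convolutional neural network. Slides are
    sampled on a rectangular grid of fixed-physical-size tiles (200 x 200
    micrometre), tiles are converted to YUV and standardized with statistics
    frozen at training time, and a small convolutional network trained by
    stochastic gradient descent scores each tile; tile probabilities are
    stitched into a slide-level probability map and thresholded into a
    binary prediction. Includes the full pixel-wise evaluation protocol
    (Dice, PPV, NPV, TPR, TNR, FPR, FNR with explicit undefined-value
    semantics, cohort aggregation, Cohen's kappa, rank-based AUC,
    cross-classifier correlation) and a seeded synthetic H&E-like slide
    generator with ground-truth masks and stain batch-effect artifacts so
    the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
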
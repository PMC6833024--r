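Package: fundusseg
Title: Optic Disc and Cup Segmentation in Fundus Images with a
    Multi-Scale Multi-Kernel U-Shaped Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage segmentation of the optic disc (OD) and optic cup
    (OC) in retinal fundus photographs, and downstream glaucoma-screening
    statistics.  Implements a U-shaped convolutional network with image
    pyramid input, multi-kernel residual modules and strided-convolution
    downsampling; a mixed-maximum-loss-minimization (MMLM) training
    strategy that re-weights hard examples with augmentation each round,
    alongside average-loss (ALM) and top-k maximal-loss (MLM) baselines;
    an OD-to-ROI-to-OC pipeline; vertical cup-to-disc ratio (VCDR), ISNT
    rim-width scoring and screening ROC-AUC; and a deterministic
    synthetic fundus-phantom generator with analytic ground truth for
    testing at desk scale.  The network, including convolution
    forward/backward passes, batch normalization and Adam, is implemented
    natively (RcppArmadillo) with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
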
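Package: lightcf
Title: Lightweight Long-Range Context Fusion Network for Polyp Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implementation of LightCF-Net, a lightweight encoder-decoder
    network for real-time polyp segmentation in colonoscopy images. The
    encoder fuses Large Kernel Attention (depth-wise, dilated depth-wise and
    pointwise convolution) with channel attention; skip connections carry a
    Visual Attention Mamba module built on a selective state-space scan; the
    bottleneck applies Pyramid Split Attention over multi-kernel group
    convolutions. Ships a self-contained compute core (reverse-mode
    automatic differentiation with C++ kernels), a compound BCE-Dice loss,
    segmentation metrics (IoU, Dice, sensitivity, specificity, accuracy,
    ROC/AUC), a seeded synthetic colonoscopy-like fixture generator,
    dataset I/O with the standard resize/crop protocol, and a training,
    evaluation and prediction pipeline with a polynomial learning-rate
    schedule and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
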
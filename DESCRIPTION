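Package: bodycomp
Title: Abdominal CT Body-Composition Segmentation and Sarcopenia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trainable U-shaped encoder-decoder networks (U-Net, Attention
    U-Net, SegNet) for segmenting subcutaneous fat, visceral fat and muscle
    in axial abdominal CT slices, together with the downstream measurement
    chain: pixel-count areas, trapezoidal slice-stack volumes, the L3
    skeletal muscle index (SMI), and cutoff-based sarcopenia screening with
    ROC/AUC and Youden-index cutoff optimization. Includes an analytic
    phantom simulator that generates CT-like slices, volumes and screening
    cohorts with exact ground truth, so the entire pipeline can be trained
    and validated without patient data. Networks and backpropagation are
    implemented natively (RcppArmadillo).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
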
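Package: SpineVCR
Title: Vertebral Segmentation and Compression-Ratio Measurement on Lateral Spine Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for automated measurement of the vertebral
    compression ratio (VCR) on lateral thoracolumbar radiographs. Provides
    radiograph pre-processing (bit-depth reduction, CLAHE, Gaussian
    denoising, aspect-preserving padding to a fixed input size with an
    invertible coordinate transform), a multi-dilated recurrent residual
    U-Net segmentation model trained with a soft dice loss and Adam,
    rule-based mask post-processing (small-component removal and
    8-neighbourhood hole filling), per-vertebra corner-landmark geometry
    with severity grading of compression, pixel-wise evaluation metrics
    (sensitivity, specificity, accuracy, dice similarity coefficient, ROC
    and precision-recall curves) and Bland-Altman agreement statistics.
    A synthetic lateral-spine phantom generator with pixel-perfect ground
    truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
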
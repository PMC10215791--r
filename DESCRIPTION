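Package: echovol
Title: Lightweight Multitask Ultrasound Bladder Volumetry with 8-Bit Quantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end automatic bladder volume measurement from biplane
    (sagittal + transverse) B-mode ultrasound images. Provides a synthetic
    speckle phantom simulator with exact ellipsoidal ground truth, a
    sub-million-parameter multitask convolutional network (shared
    inverted-residual backbone, quantization-friendly squeeze-and-excitation
    segmentation decoder, global-pooled detection head) with staged
    freeze/train/merge optimization, quantization-aware training and 8-bit
    post-quantization, a chord-based biplane axis detector with
    shape-coefficient volume estimation, and evaluation utilities (Dice,
    confusion matrices, volume error statistics). Network compute kernels
    (im2col convolution, depthwise convolution, bilinear resampling and their
    adjoints) are implemented in 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    optparse,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
SystemRequirements: C++17
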
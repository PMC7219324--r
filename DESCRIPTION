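Package: pmbscn
Title: Dual-Pathway Spatiotemporal Convolutional Networks for Pig Behavior Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, trains and evaluates PMB-SCN, a SlowFast-style dual-pathway
    3D residual convolutional network that classifies short single-animal video
    clips into five pig behaviors (feeding, lying, motoring, scratching,
    mounting). Includes clip and manifest I/O (uncompressed AVI and PNG frame
    directories), a synthetic behavior-video generator whose classes are
    separable by their spatiotemporal signatures, the 64-frame dual-pathway
    clip sampler and the 30-view (10 temporal x 3 spatial) inference protocol,
    He-style initialization with a warm-up plus half-period cosine learning
    rate schedule for SGD training, and confusion-matrix based evaluation
    (top-1 accuracy, views accuracy, per-class rates). The 3D convolution and
    pooling kernels are implemented in C++ via Rcpp and Armadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
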
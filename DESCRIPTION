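Package: bloomdet
Title: Lightweight Flower and Bud Detection Toolkit for Orchard Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing lightweight one-stage flower
    detectors for orchard phenotyping. Provides declarative layer graphs for
    YOLOv4 and its depthwise-separable and MobileNetv3 variants with exact
    analytic parameter and FLOP accounting, IoU-distance k-means anchor
    clustering with elbow-based model selection, Cutout and Mosaic data
    augmentation, Pascal VOC / YOLO annotation interchange, VOC-style
    mAP and F1 evaluation with density stratification, per-image flower and
    bud counting, a synthetic orchard-scene generator with exact ground
    truth, and a small native runtime for smoke-scale training of the
    lightweight variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
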
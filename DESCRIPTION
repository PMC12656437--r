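Package: hsinspect
Title: Hyperspectral Inspection of Pork Belly for Foreign Object Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end near-infrared hyperspectral inspection pipeline for
    detecting foreign objects on pork belly moving along a conveyor belt.
    Provides ENVI hypercube input/output, dark/flat flat-field calibration,
    spectral band trimming and per-pixel normalization, tile-wise dense
    segmentation with a lightweight Vision Transformer trained under a
    cost-sensitive label-smoothed cross-entropy, spectral-rule and
    morphological false-positive suppression, blob/pixel/image-level
    evaluation, and a synthetic scene generator emulating 13 material
    classes, fixed-pattern stripe noise, temperature and exposure drift,
    shadows, and thin contaminants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
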
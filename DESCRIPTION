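Package: octchoroid
Title: Automated Texture Analysis of the Choroid in Fundus OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automatic pipeline for quantitative analysis of the
    choroid in optical coherence tomography (OCT) B-scans of the eye
    fundus: robust detection of the retinal pigment epithelium (RPE)
    layer, sub-RPE flattening, brightness-uniformity correction, a
    multiscale morphological filter bank with conditional erosion and
    dilation, a 20-dimensional object-texture feature vector, and a CART
    classifier with one-standard-error cost-complexity pruning and
    feature-subset search that distinguishes three choroidal imaging
    types (shadow layouts under retinal lesions, global brightness
    reduction, uniform texture). Includes a synthetic B-scan generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rpart,
    pROC,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
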
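Package: flybow
Title: Spatial Sparse Bag-of-Visual-Words for Embryo Expression Pattern Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sparse spatial bag-of-visual-words representations for
    standardized two-dimensional gene-expression pattern images, such as whole
    embryo in situ hybridization images. Dense overlapping circular patches are
    described with an upright SIFT descriptor, quantized against a k-means
    visual codebook either by hard nearest-word assignment or by a non-negative
    L1-regularized sparse code ("visual sentence"), and pooled into global or
    grid-partitioned (spatial) histograms per image and per image group.
    Includes a multi-label annotation protocol (one-vs-rest linear SVM,
    stratified 1:1 split repetitions, AUC / macro-F1 / sensitivity /
    specificity, optional positive-class over-sampling), top-k cosine-similarity
    image retrieval, a synthetic embryo-image generator for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    e1071,
    glmnet,
    jsonlite,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
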
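Package: PDL1score
Title: Multistage Ensemble Scoring of PD-L1 Tumor Proportion on IHC Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated PD-L1 tumor proportion scoring for bright-field
    immunohistochemistry image tiles. Implements point-supervised cellular
    localization with a weighted pixel-wise cross-entropy loss, compact
    fully convolutional localization and tumor-region segmentation networks
    trained with momentum SGD, multiplicative tumor-probability masking of
    the cell maps (the multistage ensemble), count-ratio TPS/IPS scoring
    with expression categories, and a concordance evaluation suite
    (object-level F1, count errors, ICC(2,1), Fleiss' kappa at clinical
    cutoffs, correlation and association tests). A seed-deterministic
    synthetic IHC tile generator with exact ground truth supports
    end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
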
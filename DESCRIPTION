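Package: pigmentr
Title: Quantification of Colony Pigmentation from Plate Images and
    Companion Expression Filters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies spatial pigmentation of bacterial patches from
    plate photographs using pixel color distances in normalized CIELAB
    space: background/foreground masking with connected-component noise
    removal and hole filling, extraction of 200-breakpoint pigmentation
    profiles across the patch axis, and baseline normalization against
    unpigmented wild-type patches with a spatially specific edge
    correction. Also provides the accompanying gene-selection procedures
    over differential-expression tables (2-standard-deviation and fixed
    fold-change rules, multi-condition shared-gene counts, biosynthetic
    gene cluster summaries with significance tests, PCA and hierarchical
    clustering of expression profiles), plus seeded synthetic plate and
    expression-table generators with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    farver,
    grDevices,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage,
    withr
Config/testthat/edition: 3
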
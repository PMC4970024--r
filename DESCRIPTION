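Package: weedvol
Title: Maize and Weed Volume Estimation from Colored 3D Field Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for depth-camera surveys of weed-infested
    maize fields. Starting from colored triangular meshes of 1 m x 1 m
    field quadrats, the package filters sensor outliers, detects the white
    sampling frame, crops and splits the scene into 0.5 m x 0.5 m
    quadrats, separates maize from weeds and soil by a dual height and
    excess-green color segmentation, estimates per-class plant volume by
    polyhedral mass properties, and relates volumes to dry biomass and
    weed density with Pearson correlation, linear regression, and
    canonical discriminant classification of weed type (monocots, dicots,
    mixtures). A synthetic field-scene generator with exact ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
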
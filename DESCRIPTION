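Package: toposmlm
Title: Topological Data Analysis for Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Point-cloud analysis of single-molecule localization microscopy
    (SMLM/dSTORM) detection tables. Provides persistence-based clustering
    (ToMATo) together with DBSCAN, Ripley's K-based and Voronoi tessellation
    clustering for benchmarking; per-cluster persistent homology on Rips
    filtrations with an uncertainty-weighted sub-sampling consensus that
    assigns a topological configuration (holes, voids) and an agreement
    score to every cluster; downstream cluster statistics and radial
    distribution profiles; a realistic dSTORM simulator with fluorophore
    blinking, localization uncertainty and false detections, emitting ground
    truth for benchmarking; and batch evaluation of segmentation accuracy.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
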
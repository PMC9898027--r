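Package: cifmapr
Title: Continuous Indexing of Fibrosis for Reticulin-Stained Marrow Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores reticulin-stained bone-marrow-trephine-like images for
    fibrosis severity on a continuous 0-1 scale using a pairwise
    (RankNet-style) learning-to-rank model over image tiles, maps scores
    across each sample, and summarises samples by average score, four-bin
    tile distribution and Shannon-entropy heterogeneity. Fibrotic hotspots
    are characterised by persistent homology of the super-level-set
    filtration of the score map (dimension 0 and 1 barcodes with an
    in-package brute-force oracle), and cohorts are embedded in a
    two-dimensional PCA disease space with random-forest subtype
    classification and rank-based group comparisons. A seeded synthetic
    reticulin-image generator with latent per-pixel severity ground truth
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    randomForest,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff
Config/testthat/edition: 3
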
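Package: mirtarsvm
Title: Two-Stage SVM Prediction of Mammalian miRNA Targets
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts mammalian microRNA targets in 3'UTR sequences with a
    high-sensitivity five-rule seed-match site filter, duplex-structure and
    energy feature extraction (113 site features in 7 groups, 30 UTR features
    in 3 groups), minimum-redundancy maximum-relevance feature ranking with
    sequential forward selection, and a two-stage cost-sensitive RBF-kernel
    support vector machine (site level followed by UTR level). Includes the
    matching evaluation statistics (ROC with an unscored-gene convention,
    precision at k, cumulative fold-change curves and their integrated area,
    binding-probability logos) and a synthetic corpus generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
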
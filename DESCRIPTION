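Package: coremarker
Title: Cross-Study Expression Meta-Analysis, Marker Selection and
    Neural-Network Sample Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies a core set of differentially expressed genes shared
    by every study in a collection of tumor-versus-normal expression
    matrices (variance filtering, probe collapse, moderated or Welch
    t-statistics, Benjamini-Hochberg adjustment, direction-consistent
    intersection), standardizes and min-max rescales expression so studies
    from different platforms share a common [0, 1] range, ranks candidate
    markers by per-gene ROC AUC subject to an immunohistochemistry
    confirmation rule, and trains a small feed-forward neural network
    classifier with an exhaustive hidden-layer architecture search to label
    samples as normal or tumor. A synthetic multi-study generator with
    planted ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
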
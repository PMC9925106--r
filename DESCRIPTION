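Package: wmds
Title: Driver Node Discovery in Differential Co-Expression Networks via
    Weighted Minimum Dominating Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate driver genes that control the state
    transition of a transcriptional co-expression network between two
    conditions. Condition-specific Pearson co-expression is computed over a
    gene-interaction reference network, per-edge differences are tested with
    a Fisher Z statistic, and the significant edges form a differential
    co-expression network. Driver nodes are then selected as a weighted
    minimum dominating set solved exactly by branch and bound, with node
    weights combining degree and the significance of incident edges. Includes
    a personalized single-sample variant, precision/recall/F-beta benchmark
    evaluation, mutation-frequency classification, and a synthetic-data
    generator with planted driver hubs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
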
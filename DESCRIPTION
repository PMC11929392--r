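Package: dsi
Title: Disentangled Successor Information Representations for Spaces and Words
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds successor-representation-based embeddings from state
    sequences. Discrete grid-world environments and random walks (or word
    corpora treated as state sequences) yield a successor representation,
    from which positive successor information (a PPMI-like matrix) is
    computed and factorized under nonnegativity plus decorrelation or
    sparsity constraints. The resulting low-dimensional vectors are analysed
    for grid-cell-like and place-cell-like spatial tuning (autocorrelogram
    gridness with a shuffling null), used for path integration via
    movement-conditional linear maps, for goal-directed navigation via a
    value proxy, recombined across barrier contexts for analogical inference
    of novel environments, and evaluated on word corpora for
    concept-specific units and vector analogies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
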
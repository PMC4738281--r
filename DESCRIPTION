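Package: barcodeDelim
Title: Species Delimitation and Diversification Analysis for DNA Barcodes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting candidate species from aligned COI DNA
    barcodes and for analysing the resulting diversity. Implements Kimura
    2-parameter distances with pairwise deletion, neighbor-joining trees with
    nonparametric bootstrap support, three species-delimitation procedures
    (distance-threshold clustering on the NJ tree, Automatic Barcode Gap
    Discovery, and the single-threshold generalized mixed Yule coalescent
    model) with a majority-rule consensus, divergence and richness summaries
    stratified by elevation, host plant and feeding site, maximum-likelihood
    diversification-rate model comparison (pure birth, birth-death, density
    dependent and two-rate Yule models with the rate-constancy statistic
    delta-AIC_RC), the relative cladogenesis test, and a coalescent-within-
    species-tree simulator that generates barcode datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape (>= 5.0),
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
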
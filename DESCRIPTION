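Package: acidnet
Title: Guide-Gene-Anchored Co-Expression Network Analysis of Fruit Acidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis anchored on a guide
    gene, built for two-genotype RNA-seq studies of fruit acidity. Identifies
    trait-associated genes as the union of differentially expressed genes
    (weighted proportions test with Benjamini-Hochberg correction) and genes
    expressed similarly to the guide, infers co-expression modules from an
    unsigned topological overlap matrix with module eigengenes and
    module-trait statistics, selects most-significant trait genes and
    intramodular hubs calibrated on the guide gene, classifies subgroup
    connectivity changes, tests annotation-term enrichment by hypergeometric
    tests, and detects module-network regulators with Gibbs-sampled
    consensus clustering and probabilistic regulator scores. Includes a
    seeded synthetic-data generator with planted modules, trait model, guide
    gene and regulators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    grDevices,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
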
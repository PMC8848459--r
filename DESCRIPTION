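Package: admixdelim
Title: Admixture-Aware Species Delimitation from Phylogenomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting candidate species in the presence of gene
    flow from target-capture phylogenomic data. Implements SNP quality
    filtering, individual ancestry estimation by regularized nonnegative
    matrix factorization with cross-entropy model choice, hybrid
    classification, gene and site concordance factors, Colless imbalance
    under the proportional-to-distinguishable-arrangements null, Patterson's
    D / f4-ratio / f-branch introgression statistics with block-jackknife
    significance, a rule-based delimitation engine, and statistics
    quantifying how admixture distorts concatenated phylogenies. A
    multispecies-coalescent simulator with pulse admixture, hybrid
    individuals, missingness and mitochondrial capture provides ground-truth
    synthetic datasets for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
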
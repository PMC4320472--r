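Package: xpopacc
Title: Accuracy of Across-Population Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and empirical accuracy of genomic prediction when
    reference individuals and selection candidates come from different
    populations. Implements selection-index based accuracy formulas for one or
    two reference populations, a population-parameter formula built on the
    effective number of chromosome segments, genomic relationship matrices
    under population-specific or pooled allele-frequency centering with
    inbreeding rescaling and regression towards the pedigree relationship
    matrix, pedigree relationship matrices with generation truncation, GREML
    variance-component estimation with GBLUP prediction, multi-population
    genetic-correlation estimation, quantitative-trait simulation with
    correlated allele substitution effects, and a gene-dropping simulator for
    multi-breed genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    readr,
    withr
Config/testthat/edition: 3
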
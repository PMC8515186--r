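Package: xoscape
Title: Crossover Calling and Recombination Landscape Analysis for F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects and scores meiotic crossovers in F2 SNP-array genotype
    matrices with a windowed transition-validation rule, builds Kosambi
    genetic maps from physical marker order, partitions recombination across
    genomic zones and relative physical bins, and compares the recombination
    landscapes of two populations with chi-squared contingency and Wilcoxon
    signed-rank tests. Ships a meiosis simulator (piecewise recombination
    landscape, gamma-renewal crossover interference, genotyping error and
    missing calls) so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
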
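Package: introscan
Title: Windowed Population Differentiation and Introgression Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window scans of population differentiation and gene
    introgression for diploid genotype panels. Implements windowed nucleotide
    diversity (pi), the Weir-Cockerham weighted F_ST estimator,
    allele-frequency-based Patterson's D and the f_d admixture-fraction
    statistic in the four-taxon configuration (((P1,P2),P3),O), outlier
    interval classification by joint F_ST and pi-ratio tails, decile
    F_ST-versus-f_d association, interval-to-gene association with flanks,
    and candidate-set intersection. Ships a Balding-Nichols four-population
    simulator with windowed introgression at known admixture fraction so
    every statistic can be tested against a known truth, plus a config-driven
    end-to-end pipeline with deterministic text outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
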
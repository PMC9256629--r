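Package: dnmtrio
Title: De Novo Mutation Analysis for Trio Sequencing Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for germline de novo mutation (DNM)
    analysis in father-mother-child trio cohorts: candidate DNM filtering from
    trio genotype calls (parental alt-read, depth and genotype-quality rules),
    multi-caller structural-variant consensus merging with size-dependent
    caller-support rules and a cross-pedigree artifact filter, clustered-
    mutation detection at 10 bp and 100 bp windows, 96-channel trinucleotide
    catalogue construction with non-negative least-squares signature fitting
    and one-signature-per-mutation assignment, and a cohort-comparison
    statistics layer (chi-square and Fisher spectrum tests, Holm adjustment,
    Kruskal-Wallis, Kolmogorov-Smirnov size spectra, negative-binomial
    exposure regression with AIC model choice, Williams overdispersed
    binomial, bootstrap rates and a design power simulation). Ships a
    synthetic-study generator with planted ground truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    MASS,
    pracma,
    vcfR,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
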
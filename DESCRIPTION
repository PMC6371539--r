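Package: epiherit
Title: Simulating Epistasis and Heritability in Relative-Pair Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for studying how additive and epistatic
    genetic architectures shape heritability estimates from relative pairs.
    Defines declarative genotype-to-trait-mean architectures (additive,
    two-locus XOR epistasis, and their composition), simulates nuclear
    family, half-sib, and cousin cohorts under Hardy-Weinberg founder
    genotypes and Mendelian transmission, estimates narrow-sense
    heritability from relative-pair correlations and from genotype-coded
    variance components, estimates broad-sense heritability, and verifies
    every stochastic estimate against an exact enumeration oracle for
    population moments and relative-pair covariances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
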
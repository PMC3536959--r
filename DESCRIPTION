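Package: exomassoc
Title: Multi-Stage Exome Sequencing Association Analysis from Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-stage sequencing-based association studies of
    common traits. Implements genotype-likelihood computation from
    quality-filtered base counts with a type-specific substitution error
    model estimated from the data, EM maximum-likelihood minor-allele
    frequency estimation under Hardy-Weinberg equilibrium with minor-allele
    uncertainty, read-level case-control likelihood-ratio testing with
    genomic control, genotype-based association with rank-normalised
    quantitative traits and principal-component covariates, Storey-type
    enrichment estimation, LD-aware follow-up SNP selection, and
    fixed-effects meta-analysis (sample-size-weighted z and
    inverse-variance schemes). A synthetic cohort generator produces
    genotypes, binary and quantitative phenotypes, and error-prone
    low-depth read counts so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
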
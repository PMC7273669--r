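Package: sharedvar
Title: Shared Variants Between Germline and Somatic Variant Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and explains the overlap between germline and somatic
    single-nucleotide variant call sets. Implements the Forbes coefficient of
    co-occurrence and its partition-conditioned generalization over nucleotide
    substitution contexts (basic class through heptamer), whitelist
    construction for a conservative universe of potential SNVs, per-context
    mutation-rate estimation with cross-setting correlations, estimation of
    germline leakage into somatic call sets from matched-normal read depth,
    and subset characterizations (context-matched downsampling, allele age,
    continent counts, ancestry crosses, VAF). Ships a synthetic exome-cohort
    generator with configurable context-dependent mutation rates so the whole
    pipeline is testable without external downloads.
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
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    Biostrings,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
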
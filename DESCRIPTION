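Package: woolymap
Title: Backcross Fine-Mapping and Splice-Consequence Analysis for a
    Recessive Coat Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the positional-candidate analysis of a fully
    penetrant recessive mouse mutation mapped in a large testcross:
    simulation of backcross panels under a Haldane (no-interference)
    meiosis model, segregation tests and recombinant-counting trait
    localization with two-stage critical-interval refinement,
    rule-based candidate-gene triage, detection of a single contiguous
    deletion from coisogenic sequence pairs with left-aligned
    normalization and gene-model overlap annotation, and prediction of
    exon-skipping consequences: mutant transcript models, RT-PCR
    amplicon lengths, translation, frameshift and protein-domain
    truncation reports. Ships a synthetic locus fixture replicating the
    structure of an overlapping two-gene locus in which one deletion is
    intronic for one gene but removes a splice acceptor of the other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
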
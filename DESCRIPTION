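Package: ascons
Title: Condition-Specific Sense-Antisense Transcription and Its Conservation
    in Budding Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and comparing antisense transcription
    from strand-specific RNA-seq in two related yeast species across culture
    conditions (mid-log, early stationary, heat shock). Calls transcript units
    from per-base strand-resolved read depth with an iterative peak-seeded
    caller, quantifies them as BPKM (bases per kilobase of gene model per
    million mapped bases), classifies units against an ORF annotation, couples
    sense ORF transcripts to opposite-strand overlapping non-coding RNAs,
    computes metagene density profiles over a canonical gene model, scores the
    cross-species conservation of sense-antisense overlap geometry, classifies
    inverse sense/antisense expression changes under stress, and tests whether
    conserved pairs are enriched for inverse expression. Ships a ground-truthed
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
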
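Package: lncscout
Title: Identification and Genomic Classification of Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a long-noncoding-RNA discovery
    pipeline for plant transcript sets. Transcripts are filtered for protein-coding
    potential by three sequential criteria (transcript length, longest complete open
    reading frame, and translated homology against a protein reference scored with
    Karlin-Altschul e-values), surviving candidates are classified as miRNA, shRNA or
    siRNA precursors by exact full-length small-RNA matching with class precedence,
    and candidates are localized in a genome relative to gene models (genic versus
    intergenic, gene-body coverage tiers, sub-genic categories, sense/antisense
    orientation). A deterministic synthetic-data generator plants ground-truth labels
    for every pipeline decision so the whole pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
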
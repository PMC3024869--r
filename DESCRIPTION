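Package: divergon
Title: Conservation-Stratified Analysis of Divergent Head-to-Head Gene Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects head-to-head (divergently transcribed) gene pairs from
    genome annotation, stratifies them into nested evolutionary-conservation
    sets via ortholog maps, and compares the strata on TSS distance,
    coexpression (Pearson/Spearman correlation, Mutual Rank, Relative Rank,
    multi-dataset significance ratios), transcription-factor sharing, and
    information-content (Resnik/Lin) Gene Ontology semantic similarity. A
    seeded synthetic-data generator produces annotations, expression matrices,
    TF maps and a toy ontology with planted effects so the full stratified
    pipeline can be run and validated end to end without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
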
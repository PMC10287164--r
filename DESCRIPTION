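Package: decapDiag
Title: Diagnosing Decapping-Driven Versus Transcription-Driven mRNA
    Changes from Parallel CAGE, RNA-Seq, Ribo-Seq and ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether mRNA up-regulation in yeast
    decapping-factor mutants reflects diminished decapping and 5'->3'
    decay or increased transcription. Implements a two-pool
    (capped/uncapped) steady-state kinetic simulator with planted ground
    truth and a limiting preinitiation-complex (PIC) translation model;
    TPM/RPKM/translational-efficiency and capped-to-total (C/T) ratio
    quantification; CAGE transcription start site clustering with
    consensus promoters and gene assignment; median-of-ratios, ERCC
    spike-in and foreign-genome ChIP spike-in size factors; a negative
    binomial Wald test for differential abundance and translational
    efficiency; and classification of genes by decapping-activator
    dependence and by decay- versus transcription-driven mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
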
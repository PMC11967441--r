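Package: earphase
Title: Comparative Ear Transcriptome Phasing and QTL/QTN Candidate Gene
    Integration for Maize Kernel Row Number
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a comparative RNA-seq candidate-gene
    workflow for maize kernel row number (KRN): negative-binomial differential
    expression between two inbred lines across five early ear developmental
    stages (V6-V10), fuzzy c-means clustering of stage trajectories with a
    data-driven contiguous two-phase partition, and integration of Phase-I
    line-specific differentially expressed genes with compiled QTL hotspots
    (intervals supported by two or more studies) and 200 kb QTN flanking
    windows to call high-probability candidate genes. Includes a synthetic-data
    generator with ground-truth labels so every stage of the pipeline is
    testable without external downloads, plus expression summarization (FPKM,
    abundance bins), sample-level QC (correlation, PCA, replicate-outlier
    flagging) and a 2^-ddCt qPCR utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    e1071,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
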
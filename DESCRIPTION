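Package: radicl
Title: RNA-Chromatin Interaction Mapping from RADICL-seq Chimeric Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing RNA And DNA Interacting Complexes Ligated
    and sequenced (RADICL-seq) data. Deconvolves chimeric single-end reads
    into RNA and DNA tags around the bridge adapter, screens ribosomal RNA,
    removes PCR duplicates, maps tags exactly on small genomes, bins the
    genome at 25-kb resolution, builds sparse RNA-by-bin contact matrices,
    and calls significant RNA-chromatin interactions with a one-sided
    cumulative binomial model and Benjamini-Hochberg correction. Downstream
    summaries cover genomic distance classes, TAD-boundary metaprofiles,
    peak density profiles, repeat-element enrichment, and cross-sample
    comparisons (Jaccard binding distance, promoter log2 ratios, shared
    trans contacts). A synthetic-data generator emulates the read anatomy
    and contact structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
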
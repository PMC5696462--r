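Package: lncscout
Title: Discovery and Positional Annotation of Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filters assembled transcript models down to long non-coding RNA
    (lncRNA) candidates through a staged coding-potential cascade (size and
    exon-count thresholds, protein-database homology, six-frame open reading
    frame length, coding-potential score, protein-domain and non-coding-family
    homology), classifies candidates into seven positional categories against
    a reference annotation, clusters them into loci, summarises their gene
    structure, calls sample-specific and differentially expressed lncRNAs from
    an FPKM matrix, and associates lncRNAs with overlapping or neighbouring
    protein-coding genes by genomic distance and Pearson co-expression. Ships
    a seeded synthetic-data generator that emulates every pipeline input with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
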
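Package: capsidSurvey
Title: Degenerate PCR Survey of Viral Major Capsid Protein Gene Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying the diversity of RNA-virus major capsid
    protein (MCP) genes by degenerate PCR amplicon sequencing, motivated by
    HcRNAV-like viruses in marine sediments. Covers degenerate primer design
    by back-translation of conserved amino-acid motifs, IUPAC-aware in-silico
    amplification, dereplication of reads into amplicon sequence variants
    (ASVs) with singleton removal and synonymous collapse to amino-acid ASVs,
    percent-identity classification against a reference panel, per-layer
    community composition, neighbor-joining phylogenies with bootstrap
    support and host-range (UA/CY) typing, and segmentation of amplicons into
    conserved and variable regions. Includes a fully seeded simulator of
    layered sediment viral communities so every stage can be validated
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    ape
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
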
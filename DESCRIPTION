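Package: plateletTx
Title: Platelet Transcriptome Landscape Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of bulk platelet RNA-seq cohorts:
    construction of an annotation hierarchy with stringently derived
    purely-intronic and unannotated-intergenic tracks, single-label
    read-category accounting, RPKM quantification with beta-actin-anchored
    expression calls, permutation-based genomic feature enrichment,
    inter-individual correlation structure (including the within- versus
    between-group contrast used for pseudogene profiles), and
    transcriptome-proteome concordance with a five-way gene partition.
    Includes a seeded synthetic-data generator that emulates the statistical
    structure of a ten-donor cohort so every stage is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
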
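Package: clipmotifs
Title: iCLIP Crosslink-Site Analysis and Multivalent Splicing-Motif
    Enrichment
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for individual-nucleotide resolution
    CLIP (iCLIP) data analysis on toy or real genomes: demultiplexing of
    barcoded reads, naive one-mismatch alignment, PCR-duplicate removal
    via random barcodes to obtain single-nucleotide crosslink sites,
    genomic region-class enrichment maps, splice-junction RNA maps,
    pentamer Z-score motif discovery against randomized crosslink
    positions, construction of regulated and control cassette-exon sets
    from differential-exon tables, and enrichment testing of multivalent
    trimer pair motifs in exon regions with Fisher's exact tests and a
    bootstrap false-discovery estimate. Includes a synthetic-data
    generator that emits every input with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    data.table,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
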
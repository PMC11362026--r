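Package: cpatag
Title: Processing and Joint Analysis of Dual-Modality Single-Cell Chromatin Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for droplet-based single-cell assays that
    capture a histone-modification profile and a chromatin-accessibility
    profile from the same cell using differently barcoded Tn5 transposases.
    Provides adapter-tag and cell-barcode demultiplexing of FASTQ read trios,
    Tn5-corrected fragment building with deduplication and cell calling,
    per-cell quality control (fragment counts, TSS enrichment, FRiP,
    nucleosomal fragment-size ladder), simplified peak calling for punctate
    insertion signal and broad sparse-enrichment domains, tile-matrix
    construction with TF-IDF/LSI embedding and clustering, and joint
    two-modality analyses: distance-weighted gene scores, classification of
    accessible-but-silenced regulatory states, base-pair co-occupancy of the
    two signal classes, alternative-TSS preference, percent-spliced-in, and
    cross-modality cluster correspondence. A built-in synthetic data
    generator with planted ground truth makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
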
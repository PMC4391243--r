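Package: tnseqr
Title: Transposon Insertion-Site Mapping and Mutant Pool Comparison
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for mapping transposon insertion sites from
    junction-fragment sequencing of saturated bacterial mutant libraries
    (Tn-seq/TraDIS-style experiments). Extracts genomic fragments downstream
    of transposon terminal motifs from raw FASTQ, filters SAM alignments by
    MD-tag mismatch count and AS-tag alignment score, calls strand-aware
    insertion positions, collapses target-site-duplication twins, joins
    positions to GFF gene annotation to produce per-gene normalized
    insertion and read statistics (NRM, NIM, centile positions, NIindex),
    calls candidate essential genes, and compares two mutant pools with a
    standardized log-proportion-ratio Z-score. Includes a seeded synthetic
    mutant-library simulator with a truth table so every stage can be
    verified end to end, and an exact-match oracle aligner for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ShortRead,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
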
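Package: circbsj
Title: Characterization of Circular RNA Back-Splice Junctions in Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing circular RNAs from back-splice
    junction tables, as produced by junction-level circRNA callers, together
    with a genome and gene annotation. Implements SRPBM normalization of
    junction-read counts, genomic-origin (exonic/intronic/intergenic) and
    exon-architecture classification, alternative-circularization locus
    statistics with dominant-isoform detection, back-splice splice-signal
    dinucleotide spectra, reverse-complementary flanking-sequence and MITE
    overlap searches, differential-expression calling with fold-change and
    FDR cut-offs, hypergeometric term enrichment of parent genes, plant-style
    miRNA target complementarity scoring with circRNA-miRNA-mRNA network
    assembly, and a fully truth-labelled synthetic data generator for testing
    every stage without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
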
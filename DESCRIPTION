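Package: regvarscreen
Title: In-Silico Screening of Cis-Regulatory Variants for Allele-Specific
    Transcription Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for prioritising candidate functional
    variants inside an associated haplotype block. Provides linkage
    disequilibrium computation and proxy-SNP selection from phased
    haplotypes, intersection of variants with chromatin-element tracks
    (DNase hypersensitivity, histone marks, TF ChIP-seq, ChromHMM states),
    position-weight-matrix scanning with relative scores, a biophysical
    occupancy (TRAP-type) affinity model with empirical p-value
    calibration against a background null, an allele-differential binding
    screen with Benjamini-Hochberg correction and motif-congruence checks,
    arithmetic-progression spacing analysis of motif anchors, and
    quantification helpers for qPCR (2^-ddCt) and dual-luciferase reporter
    read-outs. A synthetic-data module generates haplotype panels with
    block-wise LD, motif-planted sequences, allelic sequence pairs and
    replicated Ct tables with known ground truth so that every stage of
    the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
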
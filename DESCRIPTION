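Package: tgloscreen
Title: Discovery of Transcribed Germline-Limited Open Reading Frames in
    Ciliate Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering transcribed
    germline-limited open reading frames (TGLOs) in ciliates with
    extensive genome rearrangement, modelled on the Oxytricha
    micronuclear/macronuclear architecture. Simulates germline genomes in
    which nanochromosome precursors (ordered, optionally scrambled
    macronuclear-destined sequences separated by internal eliminated
    sequences) are embedded in germline-limited sequence, together with
    whole-cell DNA, developmental RNA time-course, small-RNA and
    template-RNA read sets. Provides exact read mapping, six-frame ORF
    scanning under the ciliate nuclear genetic code, Monte Carlo locus
    shuffling to calibrate coverage thresholds over germline-limited
    space, classification of candidates into high- and low-transcription
    TGLO sets, greedy telomere-seeded assembly of nanochromosomes from
    reads with MDS decomposition and telomere-addition-site detection,
    and feature-class quantification (median-of-ratios normalization,
    log2 expression matrices, RPKM, two-sample Kolmogorov-Smirnov
    comparisons, strain retention calls).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
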
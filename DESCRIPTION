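Package: splicejudge
Title: Splice Junction Discovery, PTC Prediction and Alternative Splicing
    Analysis for NMD Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a combinatorial exon-exon junction database from gene
    models, assigns single-end RNA-seq reads to junctions (with iterative
    3' read truncation rescue), quantifies junction usage between two
    conditions (RPKM, upper-quartile and TMM normalization, fold-change
    regulation calls), predicts premature termination codons (PTC) under
    the 50-nucleotide rule of nonsense-mediated mRNA decay (NMD),
    classifies alternative splicing events into seven classes (SES, MES,
    A5SS, A3SS, MXE, AFE, ALE) with percent-spliced-in quantification,
    and computes conservation meta-profiles and stop-codon identity
    statistics around regulated events. Includes a fully specified
    synthetic-data generator (genome, annotation, WT/KO read sets,
    conservation track) with ground truth, emulating NMD-deficient
    stabilization of PTC+ isoforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    edgeR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
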
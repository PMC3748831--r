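Package: denovoquant
Title: Quality Control, Spike-In Calibration and Transcript Families for
    De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative de novo transcriptome studies of
    non-model organisms. Implements a two-phase paired-end read quality
    control cascade (adapter clipping, alignment-free rRNA/mtRNA
    contaminant screening by canonical k-mers, low-complexity removal,
    positional prefix trimming, adaptive sliding-window 3' quality
    trimming) with full read/base attrition accounting; fragment counting
    and FPKM computation from alignment tables; absolute quantification of
    transcripts in molecules per embryo via ERCC spike-in standard curves
    fitted by ordinary least squares or Huber robust regression;
    single-linkage transcript-family clustering from filtered BLAST
    tabular hits with family-level expression summation, genome-fraction
    estimates and assembly summary statistics; and a synthetic-data
    generator producing every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    igraph,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
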
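Package: scMethTx
Title: Single-Cell Methylome and Transcriptome Comparison of Two-Group Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of single-cell bisulfite sequencing (scBS-seq) and
    single-cell RNA-seq data from a two-group design, modelled on low- versus
    high-competence oocyte studies. Provides readers for Bismark-style coverage
    files, BED feature annotations and count matrices; cell-level quality
    control gates for both omics; region-level methylation quantification over
    CpG islands, promoters, gene bodies, transposons, 1-kb windows and variably
    methylated regions; a filter-cascade differential-methylation caller with
    per-group hyper/hypomethylation labelling; a negative-binomial differential
    expression test with median-of-ratios normalization and BH-FDR; joint
    non-negative matrix factorization of the two omics layers with
    factor-marker ranking and distance-constrained methylation-expression
    correlation; and a seeded synthetic-data generator emulating sparse
    (0.5-3x) single-cell methylomes and NB-distributed counts so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
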
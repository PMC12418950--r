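#' Per-cell RNA quality-control metrics
#'
#' Computes, for each cell: the library read total (`n_reads`, from supplied
#' metadata or defaulting to column sums), the number of detected genes
#' (count > 0), the total molecule count, and the mitochondrial percentage.
#' An all-zero cell gets `pct_mito = 0` with a warning; if the annotation has
#' no mitochondrial genes, `pct_mito` is 0 everywhere.
#'
#' @param counts genes x cells integer matrix
#' @param gene_table internal genes table with an `is_mito` flag
#' @param read_counts optional named vector of per-cell read totals; names
#'   must match the matrix columns
#' @return a `data.table` with one row per cell: `cell_id`, `n_reads`,
#'   `n_genes_detected`, `n_counts`, `pct_mito`
#' @export
rna_cell_qc <- function(counts, gene_table, read_counts = NULL) {
  cells <- colnames(counts)
  n_counts <- colSums(counts)
  if (is.null(read_counts)) {
    n_reads <- n_counts
  } else {
    if (!setequal(names(read_counts), cells)) {
      stop("cell ids in read_counts do not match the count matrix")
    }
    n_reads <- as.numeric(read_counts[cells])
  }
  mito_ids <- gene_table$gene_id[gene_table$is_mito]
  mito_rows <- rownames(counts) %in% mito_ids
  mito_counts <- if (any(mito_rows)) {
    colSums(counts[mito_rows, , drop = FALSE])
  } else {
    rep(0, length(cells))
  }
  zero <- n_counts == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) have zero total counts; pct_mito set to 0")
  }
  pct_mito <- ifelse(zero, 0, 100 * mito_counts / n_counts)
  data.table(
    cell_id = cells,
    n_reads = n_reads,
    n_genes_detected = colSums(counts > 0),
    n_counts = as.numeric(n_counts),
    pct_mito = pct_mito
  )
}

#' Default RNA cell-filter thresholds
#'
#' The full-scale defaults: keep a cell iff it has at least `min_reads` reads
#' and `min_genes` detected genes, at most `max_genes` detected genes and
#' `max_counts` molecules, and mitochondrial percentage at most `max_pct_mito`.
#' Lower bounds are inclusive (>=), upper bounds inclusive (<=). For
#' reduced-scale synthetic genomes pass thresholds matched to the simulated
#' library size.
#'
#' @param min_reads,min_genes lower bounds (inclusive)
#' @param max_genes,max_counts,max_pct_mito upper bounds (inclusive)
#' @return a named list of thresholds
#' @export
rna_qc_thresholds <- function(min_reads = 25000, min_genes = 5000,
                              max_genes = 7500, max_counts = 2e6,
                              max_pct_mito = 5) {
  list(min_reads = min_reads, min_genes = min_genes, max_genes = max_genes,
       max_counts = max_counts, max_pct_mito = max_pct_mito)
}

#' Filter RNA cells on the conjunctive QC rules
#'
#' Rules are conjunctive, so the kept set is independent of evaluation order;
#' every excluded cell lists each violated rule.
#'
#' @param qc result of [rna_cell_qc()]
#' @param thresholds a [rna_qc_thresholds()] list
#' @return `list(kept, reasons)`: kept cell ids, and a table of per-cell
#'   pass/fail with a semicolon-separated `reasons` string
#' @export
filter_rna_cells <- function(qc, thresholds = rna_qc_thresholds()) {
  th <- thresholds
  checks <- cbind(
    qc$n_reads < th$min_reads,
    qc$n_genes_detected < th$min_genes,
    qc$n_genes_detected > th$max_genes,
    qc$n_counts > th$max_counts,
    qc$pct_mito > th$max_pct_mito
  )
  labels <- c(
    sprintf("n_reads<%g", th$min_reads),
    sprintf("n_genes_detected<%g", th$min_genes),
    sprintf("n_genes_detected>%g", th$max_genes),
    sprintf("n_counts>%g", th$max_counts),
    sprintf("pct_mito>%g", th$max_pct_mito)
  )
  reasons <- apply(checks, 1L, function(v) paste(labels[v], collapse = ";"))
  keep <- rowSums(checks) == 0L
  list(
    kept = qc$cell_id[keep],
    reasons = data.table(cell_id = qc$cell_id, pass = keep, reasons = reasons)
  )
}

#' Per-cell bisulfite quality-control metrics
#'
#' For each cell: the number of distinct CpG sites with coverage, and the
#' global CpG methylation percentage (pooled reads:
#' `100 * sum(n_meth) / sum(n_meth + n_unmeth)`).
#'
#' @param cells named list of per-cell call tables
#' @return a `data.table` with `cell_id`, `n_cpgs_covered`, `global_meth_pct`
#' @export
bs_cell_qc <- function(cells) {
  data.table(
    cell_id = names(cells),
    n_cpgs_covered = vapply(cells, nrow, integer(1)),
    global_meth_pct = vapply(cells, function(x) {
      tot <- sum(x$n_meth) + sum(x$n_unmeth)
      if (tot == 0) return(NA_real_)
      100 * sum(x$n_meth) / tot
    }, numeric(1))
  )
}

#' Filter bisulfite cells
#'
#' Keeps a cell iff it covers at least `min_cpgs` CpG sites and its global
#' methylation lies strictly inside `(meth_low, meth_high)` percent — cells at
#' exactly the window edge are discarded, as are cells outside it. The
#' full-genome default for `min_cpgs` is 500 000; scale it to the genome when
#' running on reduced synthetic data.
#'
#' @param qc result of [bs_cell_qc()]
#' @param min_cpgs minimum covered CpG sites (inclusive)
#' @param meth_low,meth_high strict global-methylation window in percent
#' @return `list(kept, reasons)` as in [filter_rna_cells()]
#' @export
filter_bs_cells <- function(qc, min_cpgs = 500000, meth_low = 30,
                            meth_high = 70) {
  checks <- cbind(
    qc$n_cpgs_covered < min_cpgs,
    is.na(qc$global_meth_pct) | qc$global_meth_pct <= meth_low,
    !is.na(qc$global_meth_pct) & qc$global_meth_pct >= meth_high
  )
  labels <- c(
    sprintf("n_cpgs_covered<%g", min_cpgs),
    sprintf("global_meth_pct<=%g", meth_low),
    sprintf("global_meth_pct>=%g", meth_high)
  )
  reasons <- apply(checks, 1L, function(v) paste(labels[v], collapse = ";"))
  keep <- rowSums(checks) == 0L
  list(
    kept = qc$cell_id[keep],
    reasons = data.table(cell_id = qc$cell_id, pass = keep, reasons = reasons)
  )
}

#' Diagnostic z-scores for TSS-proximal methylation
#'
#' An optional diagnostic (never an exclusion rule): mean methylation in
#' TSS +/- 1 kb per cell, standardised across cells; |z| > 3 flags a cell as
#' having an atypical promoter-proximal methylation profile.
#'
#' @param cells named list of per-cell call tables
#' @param gene_table internal genes table
#' @return a `data.table` with `cell_id`, `tss_meth`, `z`, `flagged`
#' @export
tss_meth_diagnostic <- function(cells, gene_table) {
  tss_regions <- data.table(
    chrom = gene_table$chrom,
    start = pmax(0L, gene_table$tss - 1000L),
    end = gene_table$tss + 1000L,
    feature_class = "promoter",
    region_id = paste0("tss_", gene_table$gene_id)
  )
  gr <- regions_to_granges(tss_regions)
  vals <- vapply(cells, function(calls) {
    hits <- GenomicRanges::findOverlaps(cpg_to_granges(calls), gr)
    idx <- unique(S4Vectors::queryHits(hits))
    if (length(idx) == 0L) return(NA_real_)
    sum(calls$n_meth[idx]) /
      (sum(calls$n_meth[idx]) + sum(calls$n_unmeth[idx]))
  }, numeric(1))
  z <- (vals - mean(vals, na.rm = TRUE)) / sd(vals, na.rm = TRUE)
  data.table(cell_id = names(cells), tss_meth = vals, z = z,
             flagged = !is.na(z) & abs(z) > 3)
}
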
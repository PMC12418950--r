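#' Tile a genome in fixed-width windows
#'
#' Non-overlapping adjacent windows covering every chromosome; the last window
#' of a chromosome may be shorter. Coordinates are 0-based half-open.
#'
#' @param genome named vector of chromosome lengths (bp)
#' @param width window width in bp (default 1000)
#' @return a regions `data.table` with feature class `window1kb`
#' @export
tile_windows <- function(genome, width = 1000L) {
  if (width <= 0) stop("width must be > 0")
  width <- as.integer(width)
  out <- lapply(names(genome), function(ch) {
    L <- as.integer(genome[[ch]])
    starts <- seq.int(0L, L - 1L, by = width)
    data.table(chrom = ch, start = starts, end = pmin(starts + width, L))
  })
  out <- data.table::rbindlist(out)
  out[, `:=`(feature_class = "window1kb",
             region_id = paste0("win:", chrom, ":", start, "-", end))]
  out[]
}

#' Aggregate per-cell CpG calls into a region x cell methylation matrix
#'
#' For every (region, cell) pair, only CpG sites with read depth at least
#' `min_cov_per_cpg` contribute. With `pooling = "reads"` (default) the
#' region methylation is the read-weighted pooled ratio
#' `sum(n_meth) / sum(n_meth + n_unmeth)` over qualifying sites; with
#' `pooling = "cpg_mean"` it is the unweighted mean of per-site fractions.
#' Pairs with no qualifying site are missing (`NA`) with zero recorded
#' coverage. A CpG belongs to a region when its cytosine position lies in
#' `[start, end)`; overlapping regions are allowed (one site may serve
#' several feature classes).
#'
#' @param cells named list of per-cell call tables
#' @param regions a regions table (any mix of feature classes)
#' @param min_cov_per_cpg minimum reads per site (default 5)
#' @param pooling `"reads"` or `"cpg_mean"`
#' @return a `region_meth` object: `regions`, `cell_ids`, and regions x cells
#'   matrices `meth_fraction`, `n_cpgs_covered`, `total_reads`
#' @export
aggregate_region <- function(cells, regions, min_cov_per_cpg = 5,
                             pooling = c("reads", "cpg_mean")) {
  pooling <- match.arg(pooling)
  if (nrow(regions) == 0L) stop("empty region set")
  regions <- as.data.table(regions)
  gr <- regions_to_granges(regions)
  R <- nrow(regions)
  C <- length(cells)
  frac <- matrix(NA_real_, R, C, dimnames = list(regions$region_id, names(cells)))
  ncpg <- matrix(0L, R, C, dimnames = dimnames(frac))
  reads <- matrix(0L, R, C, dimnames = dimnames(frac))
  for (j in seq_len(C)) {
    calls <- cells[[j]]
    cov <- calls$n_meth + calls$n_unmeth
    ok <- cov >= min_cov_per_cpg
    if (!any(ok)) next
    sub <- calls[ok]
    hits <- GenomicRanges::findOverlaps(cpg_to_granges(sub), gr)
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    nm <- sub$n_meth[q]
    nt <- nm + sub$n_unmeth[q]
    agg_nm <- rowsum(as.numeric(nm), s)
    agg_nt <- rowsum(as.numeric(nt), s)
    idx <- as.integer(rownames(agg_nm))
    ncpg[idx, j] <- as.integer(rowsum(rep(1L, length(s)), s))
    reads[idx, j] <- as.integer(agg_nt)
    if (pooling == "reads") {
      frac[idx, j] <- agg_nm / agg_nt
    } else {
      frac[idx, j] <- as.vector(rowsum(nm / nt, s)) /
        as.vector(rowsum(rep(1, length(s)), s))
    }
  }
  structure(
    list(regions = regions, cell_ids = names(cells),
         meth_fraction = frac, n_cpgs_covered = ncpg, total_reads = reads),
    class = "region_meth"
  )
}

#' @export
print.region_meth <- function(x, ...) {
  cat("region_meth:", nrow(x$regions), "regions x", length(x$cell_ids),
      "cells;", round(100 * mean(is.na(x$meth_fraction)), 1),
      "% missing entries\n")
  cat("feature classes:",
      paste(unique(x$regions$feature_class), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a region_meth object by region index or feature class
#' @param x a `region_meth`
#' @param i logical/integer region index, or a feature-class name
#' @return a `region_meth` restricted to the selected regions
#' @export
subset_regions <- function(x, i) {
  if (is.character(i) && length(i) == 1L && i %in% .CLASS_VOCAB) {
    i <- x$regions$feature_class == i
  }
  structure(
    list(regions = x$regions[i],
         cell_ids = x$cell_ids,
         meth_fraction = x$meth_fraction[i, , drop = FALSE],
         n_cpgs_covered = x$n_cpgs_covered[i, , drop = FALSE],
         total_reads = x$total_reads[i, , drop = FALSE]),
    class = "region_meth"
  )
}

#' Detect variably methylated regions from a window-level matrix
#'
#' Ranks genome windows by across-cell variance of their methylation fraction
#' and merges runs of adjacent selected windows into variable-length VMRs.
#' Windows observed in fewer than `min_cells` cells are ineligible. The top
#' `top_fraction` of eligible windows by variance is selected; merged VMRs are
#' ranked by their maximum window variance.
#'
#' @param window_matrix a `region_meth` over genome windows
#' @param top_fraction fraction of eligible windows to select (default 0.02)
#' @param min_cells minimum cells with data per window (default half the
#'   cells)
#' @return a regions `data.table` of class-`VMR` intervals with `variance`
#'   and `rank` columns, ordered by rank
#' @export
detect_vmrs <- function(window_matrix, top_fraction = 0.02,
                        min_cells = NULL) {
  x <- window_matrix
  if (is.null(min_cells)) min_cells <- ceiling(length(x$cell_ids) / 2)
  n_obs <- rowSums(!is.na(x$meth_fraction))
  eligible <- n_obs >= min_cells
  if (!any(eligible)) {
    warning("no eligible windows for VMR detection")
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      feature_class = character(), region_id = character(),
                      variance = numeric(), rank = integer()))
  }
  v <- apply(x$meth_fraction, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) return(NA_real_)
    var(r)
  })
  v[!eligible] <- NA_real_
  n_sel <- max(1L, floor(sum(eligible) * top_fraction))
  cut <- sort(v[eligible], decreasing = TRUE)[n_sel]
  sel <- which(!is.na(v) & v >= cut)
  win <- x$regions[sel]
  win[, variance := v[sel]]
  data.table::setorder(win, chrom, start)
  # merge runs of adjacent selected windows
  new_run <- c(TRUE, !(win$chrom[-1L] == win$chrom[-nrow(win)] &
                         win$start[-1L] == win$end[-nrow(win)]))
  win[, run_id := cumsum(new_run)]
  vmrs <- win[, .(chrom = chrom[1L], start = min(start), end = max(end),
                  variance = max(variance)), by = run_id]
  data.table::setorder(vmrs, -variance)
  vmrs[, `:=`(rank = seq_len(.N),
              feature_class = "VMR",
              region_id = paste0("vmr:", chrom, ":", start, "-", end),
              run_id = NULL)]
  vmrs[, c("chrom", "start", "end", "feature_class", "region_id",
           "variance", "rank"), with = FALSE]
}

#' Report methylation stability of imprinted gDMRs across groups
#'
#' Imprinted germline DMRs are expected to keep their methylation state
#' whatever the maturation condition. For every imprinted region this reports
#' the two group means and their difference, flagging the region as
#' "appropriate" when the absolute difference is at most `tolerance`. This is
#' a descriptive report, not a statistical test.
#'
#' @param matrix_ a `region_meth` containing `imprinted_gDMR` regions (or a
#'   matrix over exactly those regions)
#' @param groups a table with `cell_id` and `group` (two levels)
#' @param tolerance maximum |difference| still deemed appropriate
#' @return a `data.table` with per-region group means, `difference` and
#'   `appropriate`
#' @export
imprint_report <- function(matrix_, groups, tolerance = 0.1) {
  x <- matrix_
  if ("imprinted_gDMR" %in% x$regions$feature_class &&
      !all(x$regions$feature_class == "imprinted_gDMR")) {
    x <- subset_regions(x, "imprinted_gDMR")
  }
  if (nrow(x$regions) == 0L ||
      !any(x$regions$feature_class == "imprinted_gDMR")) {
    return(data.table(region_id = character(), mean_g1 = numeric(),
                      mean_g2 = numeric(), difference = numeric(),
                      appropriate = logical()))
  }
  g <- groups$group[match(x$cell_ids, groups$cell_id)]
  lv <- sort(unique(g))
  stopifnot(length(lv) == 2L)
  m1 <- rowMeans(x$meth_fraction[, g == lv[1], drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(x$meth_fraction[, g == lv[2], drop = FALSE], na.rm = TRUE)
  data.table(
    region_id = x$regions$region_id,
    mean_g1 = m1, mean_g2 = m2, difference = m1 - m2,
    appropriate = !is.na(m1) & !is.na(m2) & abs(m1 - m2) <= tolerance
  )
}

#' Promoter regions from a gene table
#'
#' The promoter of a gene is the symmetric +/-2 kb window around its TSS,
#' clipped to the chromosome; strand does not change the window.
#'
#' @param gene_table internal genes table
#' @param genome named chromosome lengths (for clipping); optional
#' @param flank half-width in bp (default 2000)
#' @return a regions `data.table` with feature class `promoter`
#' @export
promoter_regions <- function(gene_table, genome = NULL, flank = 2000L) {
  end <- gene_table$tss + flank
  if (!is.null(genome)) end <- pmin(end, genome[gene_table$chrom])
  data.table(
    chrom = gene_table$chrom,
    start = pmax(0L, gene_table$tss - as.integer(flank)),
    end = as.integer(end),
    feature_class = "promoter",
    region_id = paste0("prom_", gene_table$gene_id),
    gene_id = gene_table$gene_id
  )
}
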
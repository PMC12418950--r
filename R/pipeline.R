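#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Recognised sections:
#' `seed`, `out_dir`, `sim` (passed to [sim_config()]), `qc` (`rna`, `bs`
#' threshold lists), `regions` (`min_cov_per_cpg`, `window_width`,
#' `vmr_top_fraction`, `pooling`), `dmr` (passed to [dm_filter_config()]),
#' `deg` (`alpha`, `lfc_min`, `min_cells`, `n_hvg`), `integration`
#' (`K`, `lambda`, `max_distance`, `r_min`, `delta_r`, `r_guard`,
#' `min_pairs`, `marker_alpha`, `marker_min_fc`). Unknown keys are rejected.
#'
#' @param x a YAML path or a list
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  known <- c("seed", "out_dir", "sim", "qc", "regions", "dmr", "deg",
             "integration")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    seed = if (is.null(x$seed)) 1L else as.integer(x$seed),
    out_dir = x$out_dir,
    sim = x$sim,
    qc = x$qc,
    regions = x$regions,
    dmr = x$dmr,
    deg = x$deg,
    integration = x$integration
  )
  sub_known <- list(
    qc = c("rna", "bs"),
    regions = c("min_cov_per_cpg", "window_width", "vmr_top_fraction",
                "pooling"),
    deg = c("alpha", "lfc_min", "min_cells", "n_hvg"),
    integration = c("K", "lambda", "max_distance", "r_min", "delta_r",
                    "r_guard", "min_pairs", "marker_alpha", "marker_min_fc")
  )
  for (sec in names(sub_known)) {
    bad <- setdiff(names(cfg[[sec]]), sub_known[[sec]])
    if (length(bad) > 0L) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.merge_args <- function(fun, user) {
  if (is.null(user)) return(do.call(fun, list()))
  do.call(fun, user)
}

#' Run the full synthetic-demo pipeline
#'
#' Executes the stages in order: simulate, QC (both omics), region
#' aggregation over every feature class plus 1-kb windows and VMR detection,
#' the DMR caller per feature class, differential expression, and the joint
#' integration (NMF factors, factor markers, methylation-expression
#' correlations). All randomness derives from `config$seed` via stable
#' per-stage seeds, so identical configs reproduce identical outputs; when
#' `config$out_dir` is set, every table is written as TSV and the manifest
#' records their md5 checksums.
#'
#' @param config a [pipeline_config()] (or list/YAML path coercible to one)
#' @return a list with per-stage results and a `manifest` (seeds, row
#'   counts, file checksums)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  t0 <- Sys.time()
  seed <- config$seed
  manifest <- list(seed = seed, stages = list())

  # --- simulate -------------------------------------------------------------
  sim_args <- config$sim
  sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_dataset(scfg)
  annotation <- sim$annotation
  manifest$stages$simulate <- list(
    n_cells_meth = length(sim$meth$cells),
    n_cells_rna = ncol(sim$expr$counts),
    n_genes = nrow(annotation$genes),
    n_regions = nrow(annotation$regions)
  )

  # --- qc -------------------------------------------------------------------
  qc_rna <- rna_cell_qc(sim$expr$counts, annotation$genes)
  rna_th <- .merge_args(rna_qc_thresholds, config$qc$rna)
  rna_filt <- filter_rna_cells(qc_rna, rna_th)
  qc_bs <- bs_cell_qc(sim$meth$cells)
  bs_args <- config$qc$bs
  if (is.null(bs_args)) bs_args <- list()
  bs_filt <- do.call(filter_bs_cells, c(list(qc = qc_bs), bs_args))
  manifest$stages$qc <- list(
    rna_kept = length(rna_filt$kept), rna_total = nrow(qc_rna),
    bs_kept = length(bs_filt$kept), bs_total = nrow(qc_bs)
  )

  # --- regions --------------------------------------------------------------
  rcfg <- config$regions
  min_cov <- if (is.null(rcfg$min_cov_per_cpg)) 5 else rcfg$min_cov_per_cpg
  width <- if (is.null(rcfg$window_width)) 1000L else rcfg$window_width
  top_fr <- if (is.null(rcfg$vmr_top_fraction)) 0.02 else rcfg$vmr_top_fraction
  pooling <- if (is.null(rcfg$pooling)) "reads" else rcfg$pooling
  cells_kept <- sim$meth$cells[bs_filt$kept]
  rmm_features <- aggregate_region(cells_kept, annotation$regions,
                                   min_cov_per_cpg = min_cov,
                                   pooling = pooling)
  windows <- tile_windows(annotation$genome, width)
  rmm_windows <- aggregate_region(cells_kept, windows,
                                  min_cov_per_cpg = min_cov,
                                  pooling = pooling)
  vmrs <- detect_vmrs(rmm_windows, top_fraction = top_fr)
  rmm_vmr <- if (nrow(vmrs) > 0L) {
    aggregate_region(cells_kept, vmrs, min_cov_per_cpg = min_cov,
                     pooling = pooling)
  } else NULL
  groups_bs <- sim$meth$groups[cell_id %in% bs_filt$kept]
  imprint <- imprint_report(rmm_features, groups_bs)
  manifest$stages$regions <- list(
    n_feature_regions = nrow(rmm_features$regions),
    n_windows = nrow(windows), n_vmrs = nrow(vmrs)
  )

  # --- dmr ------------------------------------------------------------------
  dmr_args <- config$dmr
  if (is.null(dmr_args)) dmr_args <- list()
  dmr_args$min_cov_per_cpg <- min_cov
  dcfg <- do.call(dm_filter_config, dmr_args)
  dmr_input <- subset_regions(
    rmm_features, rmm_features$regions$feature_class != "imprinted_gDMR")
  dmrs <- call_dmrs(dmr_input, groups_bs, dcfg)
  dmr_summary <- summarize_dmrs(dmrs)
  manifest$stages$dmr <- list(
    n_retained = nrow(dmrs), n_significant = sum(dmrs$significant)
  )

  # --- deg ------------------------------------------------------------------
  decfg <- config$deg
  counts_kept <- sim$expr$counts[, rna_filt$kept, drop = FALSE]
  groups_rna <- sim$expr$groups[cell_id %in% rna_filt$kept]
  de <- de_analysis(
    counts_kept, groups_rna,
    alpha = if (is.null(decfg$alpha)) 0.05 else decfg$alpha,
    lfc_min = if (is.null(decfg$lfc_min)) 2 else decfg$lfc_min,
    min_cells = if (is.null(decfg$min_cells)) 3 else decfg$min_cells
  )
  n_hvg <- if (is.null(decfg$n_hvg)) min(2000L, nrow(counts_kept)) else
    decfg$n_hvg
  hvg <- suppressWarnings(select_hvg(counts_kept, n = n_hvg))
  pca <- pca_embed(counts_kept, hvg,
                   n_components = min(2L, length(rna_filt$kept) - 1L))
  manifest$stages$deg <- list(
    n_tested = de$n_genes_tested,
    n_up = unname(de$summary["n_up"]), n_down = unname(de$summary["n_down"])
  )

  # --- integrate ------------------------------------------------------------
  icfg <- config$integration
  geti <- function(key, default) {
    if (is.null(icfg[[key]])) default else icfg[[key]]
  }
  common <- intersect(rna_filt$kept, bs_filt$kept)
  integration <- NULL
  if (length(common) >= 4L) {
    sf <- size_factors(counts_kept)
    expr_norm <- log1p(sweep(counts_kept, 2L, sf, "/"))[, common, drop = FALSE]
    loci_classes <- c("promoter", "CGI")
    meth_loci <- subset_regions(
      rmm_features, rmm_features$regions$feature_class %in% loci_classes)
    if (!is.null(rmm_vmr)) {
      meth_loci <- structure(list(
        regions = rbind(meth_loci$regions, rmm_vmr$regions, fill = TRUE),
        cell_ids = meth_loci$cell_ids,
        meth_fraction = rbind(meth_loci$meth_fraction, rmm_vmr$meth_fraction),
        n_cpgs_covered = rbind(meth_loci$n_cpgs_covered,
                               rmm_vmr$n_cpgs_covered),
        total_reads = rbind(meth_loci$total_reads, rmm_vmr$total_reads)
      ), class = "region_meth")
    }
    meth_common <- structure(list(
      regions = meth_loci$regions, cell_ids = common,
      meth_fraction = meth_loci$meth_fraction[, common, drop = FALSE],
      n_cpgs_covered = meth_loci$n_cpgs_covered[, common, drop = FALSE],
      total_reads = meth_loci$total_reads[, common, drop = FALSE]
    ), class = "region_meth")
    X_meth <- impute_region_means(meth_common)
    model <- joint_nmf(expr_norm, X_meth, K = geti("K", 2L),
                       lambda = geti("lambda", 1),
                       seed = stage_seed(seed, "integration"))
    markers_rna <- rank_factor_markers(model, expr_norm,
                                       alpha = geti("marker_alpha", 0.05),
                                       min_fc = geti("marker_min_fc", 0.25))
    markers_meth <- rank_factor_markers(model, X_meth,
                                        alpha = geti("marker_alpha", 0.05),
                                        min_fc = geti("marker_min_fc", 0.25))
    groups_common <- sim$meth$groups[cell_id %in% common]
    corr <- correlate_meth_expr(
      meth_common, expr_norm, annotation$genes, groups_common,
      max_distance = geti("max_distance", 500000),
      r_min = geti("r_min", 0.5), delta_r = geti("delta_r", 0.1),
      r_guard = geti("r_guard", 0.2), min_pairs = geti("min_pairs", 5))
    integration <- list(model = model, markers_rna = markers_rna,
                        markers_meth = markers_meth, correlations = corr,
                        cells = common)
    manifest$stages$integrate <- list(
      n_cells = length(common),
      n_markers_rna = nrow(markers_rna),
      n_markers_meth = nrow(markers_meth),
      n_correlations = nrow(corr$records)
    )
  }

  res <- list(
    config = config, annotation = annotation, sim = sim,
    qc = list(rna = qc_rna, rna_filter = rna_filt, bs = qc_bs,
              bs_filter = bs_filt),
    regions = list(features = rmm_features, windows = rmm_windows,
                   vmrs = vmrs, vmr_matrix = rmm_vmr, imprint = imprint),
    dmr = list(results = dmrs, summary = dmr_summary),
    deg = de, hvg = hvg, pca = pca,
    integration = integration
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      p <- file.path(config$out_dir, name)
      write_results_table(obj, p)
      p
    }
    files <- c(
      wr(qc_rna, "qc_rna.tsv"),
      wr(rna_filt$reasons, "qc_rna_filter.tsv"),
      wr(qc_bs, "qc_bs.tsv"),
      wr(bs_filt$reasons, "qc_bs_filter.tsv"),
      wr(vmrs, "vmrs.tsv"),
      wr(imprint, "imprint_report.tsv"),
      wr(dmrs, "dmr_results.tsv"),
      wr(dmr_summary, "dmr_summary.tsv"),
      wr(de$results, "deg_results.tsv"),
      wr(data.table(gene_id = hvg), "hvg.tsv"),
      wr(data.table(cell_id = rownames(pca$scores), pca$scores),
         "pca_scores.tsv")
    )
    if (!is.null(integration)) {
      files <- c(
        files,
        wr(data.table(cell_id = colnames(integration$model$H),
                      t(integration$model$H),
                      factor = integration$model$factor_assignment),
           "factors.tsv"),
        wr(integration$markers_rna, "markers_rna.tsv"),
        wr(integration$markers_meth, "markers_meth.tsv"),
        wr(integration$correlations$records, "correlations.tsv"),
        wr(integration$correlations$sign_counts, "correlation_summary.tsv")
      )
    }
    manifest$checksums <- tools::md5sum(files)
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$manifest <- manifest
  res
}

#' Human-readable pipeline summary
#'
#' One text block summarising QC pass counts, DMR and DEG totals, factor
#' sizes and correlation sign counts from a [run_pipeline()] result.
#'
#' @param result a [run_pipeline()] result
#' @return the summary, invisibly (it is also printed)
#' @export
pipeline_report <- function(result) {
  m <- result$manifest$stages
  lines <- c(
    "== pipeline summary ==",
    sprintf("RNA cells kept: %d / %d", m$qc$rna_kept, m$qc$rna_total),
    sprintf("BS cells kept: %d / %d", m$qc$bs_kept, m$qc$bs_total),
    sprintf("regions: %d feature regions, %d windows, %d VMRs",
            m$regions$n_feature_regions, m$regions$n_windows,
            m$regions$n_vmrs),
    sprintf("DMRs: %d retained, %d significant",
            m$dmr$n_retained, m$dmr$n_significant),
    sprintf("DEGs: %d up, %d down of %d tested",
            m$deg$n_up, m$deg$n_down, m$deg$n_tested)
  )
  if (!is.null(result$integration)) {
    tab <- table(result$integration$model$factor_assignment)
    lines <- c(
      lines,
      sprintf("integration: %d cells in %d factors (%s)",
              m$integrate$n_cells, length(tab),
              paste(sprintf("factor %s: %d", names(tab), tab),
                    collapse = ", ")),
      sprintf("correlations retained: %d", m$integrate$n_correlations)
    )
    sc <- result$integration$correlations$sign_counts
    if (nrow(sc) > 0L) {
      lines <- c(lines, sprintf(
        "  group %s: %d positive, %d negative",
        sc$group, sc$positive, sc$negative))
    }
  } else {
    lines <- c(lines, "integration: skipped (too few shared cells)")
  }
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}
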
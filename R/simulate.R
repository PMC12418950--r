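#' Configuration for the two-group synthetic dataset generator
#'
#' Defaults emulate the study design the package targets: two groups of 16
#' cells, sparse CpG capture at 0.5-3x depth, global CpG methylation near 47%,
#' beta-binomial methylation noise, and negative-binomial counts with a small
#' mitochondrial gene set. Every random draw is fixed by `seed`.
#'
#' @param seed integer seed fixing all draws
#' @param n_cells_per_group cells per group (default 16)
#' @param n_chrom,chrom_length genome layout (chromosomes of equal length, bp)
#' @param n_genes,n_cgis,n_transposons,n_imprinted annotated feature counts
#' @param n_mito_genes genes flagged mitochondrial
#' @param cpg_spacing mean distance between simulated CpG sites (bp)
#' @param baseline_meth mean global CpG methylation fraction (default 0.47)
#' @param meth_concentration Beta concentration of per-window latent means
#'   around `baseline_meth` (higher = flatter methylome)
#' @param coverage_mean mean reads per covered CpG (shifted Poisson, >= 1)
#' @param cpg_capture_rate fraction of CpG sites covered per cell
#' @param bb_dispersion beta-binomial overdispersion rho in (0,1); 0 gives
#'   pure binomial sampling
#' @param n_dmrs_planted,dmr_delta planted DMRs (signed, alternating) and
#'   their group-1 methylation shift
#' @param dmr_target_class feature class receiving planted DMRs
#' @param n_degs_planted,deg_log2fc planted DEGs (signed, alternating)
#' @param expression_meanlog,expression_sdlog log-normal law of gene means
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2)
#' @param libsize_lognormal_sigma per-cell library-size spread
#' @param mito_fraction expected fraction of counts from mito genes
#' @param n_coupled_pairs promoters whose methylation drives expression of
#'   their gene in group 1 only (negative coupling)
#' @param coupling_slope log-expression change per unit methylation fraction
#' @param n_outlier_mito,n_outlier_small extra RNA cells violating QC gates
#'   (high-mito, tiny-library)
#' @param n_outlier_hypo,n_outlier_lowcov extra BS cells violating QC gates
#'   (25% global methylation, low CpG capture)
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_group = 16L,
                       n_chrom = 2L,
                       chrom_length = 400000L,
                       n_genes = 60L,
                       n_cgis = 40L,
                       n_transposons = 20L,
                       n_imprinted = 4L,
                       n_mito_genes = 13L,
                       cpg_spacing = 60L,
                       baseline_meth = 0.47,
                       meth_concentration = 6,
                       coverage_mean = 3,
                       cpg_capture_rate = 0.3,
                       bb_dispersion = 0.2,
                       n_dmrs_planted = 0L,
                       dmr_delta = 0.4,
                       dmr_target_class = "CGI",
                       n_degs_planted = 0L,
                       deg_log2fc = 2.5,
                       expression_meanlog = log(20),
                       expression_sdlog = 1,
                       nb_dispersion = 0.3,
                       libsize_lognormal_sigma = 0.3,
                       mito_fraction = 0.02,
                       n_coupled_pairs = 0L,
                       coupling_slope = 3,
                       n_outlier_mito = 0L,
                       n_outlier_small = 0L,
                       n_outlier_hypo = 0L,
                       n_outlier_lowcov = 0L) {
  cfg <- as.list(environment())
  frac <- c("baseline_meth", "cpg_capture_rate", "bb_dispersion",
            "mito_fraction")
  for (f in frac) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  }
  if (cfg$coverage_mean < 1) stop("coverage_mean must be >= 1")
  ints <- c("n_cells_per_group", "n_chrom", "n_genes", "n_cgis",
            "n_transposons", "n_imprinted", "n_mito_genes", "n_dmrs_planted",
            "n_degs_planted")
  for (f in ints) if (cfg[[f]] < 0) stop(f, " must be >= 0")
  if (cfg$n_imprinted > cfg$n_cgis) stop("n_imprinted cannot exceed n_cgis")
  if (cfg$n_mito_genes >= cfg$n_genes) stop("n_mito_genes must be < n_genes")
  check_feature_class(cfg$dmr_target_class)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the synthetic genome annotation
#'
#' Lays out non-overlapping gene bodies on each chromosome with alternating
#' strand, symmetric +/-2 kb promoters around each TSS, CpG islands split
#' between promoter-associated and intergenic placements, intergenic
#' transposons, and a subset of CGIs flagged as imprinted germline DMRs.
#'
#' @param config a [sim_config()]
#' @return `list(genes, regions, genome)`: internal 0-based gene table,
#'   a combined regions table over all feature classes, and a named vector of
#'   chromosome lengths
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  n_chrom <- config$n_chrom
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(n_chrom))
  genome <- setNames(rep(L, n_chrom), chroms)

  per_chrom <- ceiling(config$n_genes / n_chrom)
  slot <- L %/% per_chrom
  if (slot < 9000L) {
    stop("chromosome too short to place ", per_chrom,
         " genes per chromosome (need >= 9 kb per gene slot)")
  }
  genes <- data.table()
  for (ci in seq_len(n_chrom)) {
    idx <- seq_len(min(per_chrom, config$n_genes - (ci - 1L) * per_chrom))
    if (length(idx) == 0L) break
    slot_start <- (idx - 1L) * slot
    gstart <- slot_start + as.integer(0.3 * slot)
    gend <- slot_start + as.integer(0.7 * slot)
    strand <- rep(c("+", "-"), length.out = length(idx))
    tss <- ifelse(strand == "+", gstart, gend - 1L)
    genes <- rbind(genes, data.table(
      gene_id = sprintf("gene_%s_%03d", chroms[ci], idx),
      chrom = chroms[ci], strand = strand,
      tss = as.integer(tss), gene_start = gstart, gene_end = gend,
      is_mito = FALSE
    ))
  }
  mito <- sample(nrow(genes), config$n_mito_genes)
  genes[mito, is_mito := TRUE]

  promoters <- data.table(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - 2000L),
    end = pmin(genome[genes$chrom], genes$tss + 2000L),
    feature_class = "promoter",
    region_id = paste0("prom_", genes$gene_id),
    gene_id = genes$gene_id
  )

  gene_bodies <- data.table(
    chrom = genes$chrom, start = genes$gene_start, end = genes$gene_end,
    feature_class = "gene_body", region_id = paste0("body_", genes$gene_id),
    gene_id = genes$gene_id
  )

  # CGIs: half sit on promoters (centred on the TSS), half intergenic
  n_cgi <- config$n_cgis
  n_prom_cgi <- min(nrow(genes), n_cgi %/% 2L)
  cgi_genes <- sample(nrow(genes), n_prom_cgi)
  cgi_w <- 600L
  cgis <- data.table(
    chrom = genes$chrom[cgi_genes],
    start = pmax(0L, genes$tss[cgi_genes] - cgi_w %/% 2L),
    end = pmin(genome[genes$chrom[cgi_genes]],
               genes$tss[cgi_genes] + cgi_w %/% 2L),
    gene_id = genes$gene_id[cgi_genes]
  )
  n_inter <- n_cgi - n_prom_cgi
  if (n_inter > 0L) {
    # intergenic gaps start at 0.8*slot within each gene slot; sample
    # (chrom, slot) pairs without replacement so placements never collide
    combos <- data.table(chrom = rep(chroms, each = per_chrom),
                         islot = rep(seq_len(per_chrom) - 1L, n_chrom))
    if (n_inter > nrow(combos)) {
      stop("chromosome too short to place ", n_inter, " intergenic CGIs")
    }
    pick <- combos[sample(nrow(combos), n_inter)]
    istart <- pick$islot * slot + as.integer(0.8 * slot)
    cgis <- rbind(cgis, data.table(
      chrom = pick$chrom, start = as.integer(istart),
      end = as.integer(istart) + cgi_w, gene_id = NA_character_
    ))
  }
  cgis[, `:=`(feature_class = "CGI",
              region_id = sprintf("cgi_%03d", seq_len(.N)))]

  n_tp <- config$n_transposons
  transposons <- data.table()
  if (n_tp > 0L) {
    combos <- data.table(chrom = rep(chroms, each = per_chrom),
                         islot = rep(seq_len(per_chrom) - 1L, n_chrom))
    if (n_tp > nrow(combos)) {
      stop("chromosome too short to place ", n_tp, " transposons")
    }
    pick <- combos[sample(nrow(combos), n_tp)]
    tstart <- pick$islot * slot + as.integer(0.05 * slot)
    transposons <- data.table(
      chrom = pick$chrom, start = as.integer(tstart),
      end = as.integer(tstart) + 400L,
      feature_class = "transposon",
      region_id = sprintf("tp_%03d", seq_len(n_tp)),
      gene_id = NA_character_
    )
  }

  imprinted <- data.table()
  if (config$n_imprinted > 0L) {
    imp <- cgis[sample(nrow(cgis), config$n_imprinted)]
    imprinted <- data.table(
      chrom = imp$chrom, start = imp$start, end = imp$end,
      feature_class = "imprinted_gDMR",
      region_id = sub("^cgi_", "gdmr_", imp$region_id),
      gene_id = imp$gene_id
    )
  }

  regions <- rbind(
    cgis[, c("chrom", "start", "end", "feature_class", "region_id", "gene_id")],
    promoters, gene_bodies, transposons, imprinted,
    fill = TRUE
  )
  list(genes = genes, regions = regions, genome = genome)
}

# latent CpG-level methylation means per group, plus the unit map used for
# cell-level beta draws (1-kb windows; planted/imprinted/coupled regions
# override the windows they span)
.meth_latent <- function(config, annotation) {
  set.seed(stage_seed(config$seed, "meth_latent"))
  genome <- annotation$genome
  regions <- annotation$regions

  sites <- data.table()
  for (ch in names(genome)) {
    n_sites <- max(1L, genome[[ch]] %/% config$cpg_spacing)
    pos <- sort(sample.int(genome[[ch]] - 1L, n_sites))
    sites <- rbind(sites, data.table(chrom = ch, pos = pos))
  }

  windows <- tile_windows(genome, 1000L)
  wmu <- rbeta(nrow(windows),
               config$baseline_meth * config$meth_concentration,
               (1 - config$baseline_meth) * config$meth_concentration)
  wmu <- pmin(pmax(wmu, 0.02), 0.98)

  # map each site to its window
  hits <- GenomicRanges::findOverlaps(cpg_to_granges(sites),
                                      regions_to_granges(windows))
  sites[, unit := NA_integer_]
  sites[S4Vectors::queryHits(hits), unit := S4Vectors::subjectHits(hits)]
  units <- data.table(unit_id = paste0("w", seq_len(nrow(windows))),
                      mu_g1 = wmu, mu_g2 = wmu)

  truth_dmr <- data.table(region_id = character(), feature_class = character(),
                          delta = numeric())
  override <- function(reg, mu1, mu2, tag) {
    # appends one override unit per region, remapping its sites
    uid <- paste0(tag, "_", reg$region_id)
    hits <- GenomicRanges::findOverlaps(cpg_to_granges(sites),
                                        regions_to_granges(reg))
    newu <- nrow(units) + seq_len(nrow(reg))
    sites[S4Vectors::queryHits(hits),
          unit := newu[S4Vectors::subjectHits(hits)]]
    units <<- rbind(units, data.table(unit_id = uid, mu_g1 = mu1, mu_g2 = mu2))
  }

  if (config$n_dmrs_planted > 0L) {
    pool <- regions[feature_class == config$dmr_target_class]
    # never plant into a region that an imprinted gDMR will override later
    imp_reg <- regions[feature_class == "imprinted_gDMR"]
    if (nrow(imp_reg) > 0L && nrow(pool) > 0L) {
      ov <- GenomicRanges::findOverlaps(regions_to_granges(pool),
                                        regions_to_granges(imp_reg))
      if (length(ov) > 0L) pool <- pool[-unique(S4Vectors::queryHits(ov))]
    }
    if (nrow(pool) < config$n_dmrs_planted) {
      stop("not enough ", config$dmr_target_class,
           " regions to plant ", config$n_dmrs_planted, " DMRs")
    }
    tgt <- pool[sample(nrow(pool), config$n_dmrs_planted)]
    sgn <- rep(c(1, -1), length.out = nrow(tgt))
    base <- runif(nrow(tgt), 0.35, 0.65)
    mu1 <- base + sgn * config$dmr_delta / 2
    mu2 <- base - sgn * config$dmr_delta / 2
    clip <- mu1 < 0.02 | mu1 > 0.98 | mu2 < 0.02 | mu2 > 0.98
    if (any(clip)) {
      warning(sum(clip), " planted DMR mean(s) clipped to [0.02, 0.98]")
      mu1 <- pmin(pmax(mu1, 0.02), 0.98)
      mu2 <- pmin(pmax(mu2, 0.02), 0.98)
    }
    override(tgt, mu1, mu2, "dmr")
    truth_dmr <- data.table(region_id = tgt$region_id,
                            feature_class = tgt$feature_class,
                            delta = mu1 - mu2)
  }

  imp <- regions[feature_class == "imprinted_gDMR"]
  if (nrow(imp) > 0L) {
    mu <- rep(c(0.95, 0.05), length.out = nrow(imp))
    override(imp, mu, mu, "imp")
  }

  truth_coupled <- data.table(region_id = character(), gene_id = character())
  if (config$n_coupled_pairs > 0L) {
    prom <- annotation$regions[feature_class == "promoter" & !is.na(gene_id)]
    # avoid promoters already overridden as planted DMRs
    prom <- prom[!gene_id %in% annotation$genes$gene_id[annotation$genes$is_mito]]
    if (nrow(prom) < config$n_coupled_pairs) {
      stop("not enough promoters to couple")
    }
    cp <- prom[sample(nrow(prom), config$n_coupled_pairs)]
    override(cp, rep(0.5, nrow(cp)), rep(0.5, nrow(cp)), "cpl")
    truth_coupled <- data.table(region_id = cp$region_id, gene_id = cp$gene_id)
  }

  list(sites = sites, units = units, truth_dmr = truth_dmr,
       truth_coupled = truth_coupled)
}

#' Simulate per-cell single-cell bisulfite methylomes
#'
#' Each 1-kb window (or planted/imprinted override region) carries a latent
#' methylation mean; per cell and unit a methylation fraction is drawn from a
#' Beta with that mean and overdispersion `bb_dispersion`, CpG sites are
#' captured independently at `cpg_capture_rate`, read depth per captured site
#' is 1 + Poisson(`coverage_mean` - 1), and methylated read counts are
#' binomial. Imprinted gDMRs sit near 0 or 1 identically in both groups;
#' planted DMRs shift group 1 against group 2 by `dmr_delta`.
#'
#' @param config a [sim_config()]
#' @param annotation result of [make_annotation()]
#' @return `list(cells, groups, truth, latent)`: named list of per-cell call
#'   tables, a cell-to-group table, the planted-DMR truth table, and the
#'   latent per-cell unit fractions for override units (used for coupling)
#' @export
simulate_methylomes <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  lat <- .meth_latent(config, annotation)
  sites <- lat$sites[!is.na(unit)]
  n_units <- nrow(lat$units)

  n <- config$n_cells_per_group
  cell_ids <- c(sprintf("g1_cell%02d", seq_len(n)),
                sprintf("g2_cell%02d", seq_len(n)))
  group <- rep(c(1L, 2L), each = n)
  # planted QC outliers appended to group 1's batch
  extra <- character()
  if (config$n_outlier_hypo > 0L) {
    extra <- c(extra, sprintf("g1_outlier_hypo%02d",
                              seq_len(config$n_outlier_hypo)))
  }
  if (config$n_outlier_lowcov > 0L) {
    extra <- c(extra, sprintf("g1_outlier_lowcov%02d",
                              seq_len(config$n_outlier_lowcov)))
  }
  cell_ids <- c(cell_ids, extra)
  group <- c(group, rep(1L, length(extra)))

  rho <- config$bb_dispersion
  cells <- vector("list", length(cell_ids))
  names(cells) <- cell_ids
  override_ids <- grep("^(dmr|imp|cpl)_", lat$units$unit_id)
  latent <- matrix(NA_real_, length(override_ids), length(cell_ids),
                   dimnames = list(lat$units$unit_id[override_ids], cell_ids))

  for (i in seq_along(cell_ids)) {
    set.seed(stage_seed(config$seed, paste0("meth_cell_", cell_ids[i])))
    hypo <- grepl("outlier_hypo", cell_ids[i])
    lowcov <- grepl("outlier_lowcov", cell_ids[i])
    mu <- if (group[i] == 1L) lat$units$mu_g1 else lat$units$mu_g2
    if (hypo) mu <- mu * (0.25 / config$baseline_meth)
    mu <- pmin(pmax(mu, 0.005), 0.995)
    if (rho > 1e-8) {
      conc <- (1 - rho) / rho
      p_unit <- rbeta(n_units, mu * conc, (1 - mu) * conc)
      # guard exact 0/1 from numerical underflow
      p_unit <- pmin(pmax(p_unit, 1e-6), 1 - 1e-6)
    } else {
      p_unit <- mu
    }
    latent[, i] <- p_unit[override_ids]

    capture <- config$cpg_capture_rate * if (lowcov) 0.05 else 1
    keep <- runif(nrow(sites)) < capture
    sub <- sites[keep]
    cov <- 1L + rpois(nrow(sub), max(config$coverage_mean - 1, 0))
    nm <- rbinom(nrow(sub), cov, p_unit[sub$unit])
    calls <- data.table(chrom = sub$chrom, pos = sub$pos,
                        n_meth = nm, n_unmeth = cov - nm)
    data.table::setkey(calls, chrom, pos)
    cells[[i]] <- calls
  }

  list(cells = cells,
       groups = data.table(cell_id = cell_ids, group = group,
                           planted_outlier = grepl("outlier", cell_ids)),
       truth = lat$truth_dmr,
       truth_coupled = lat$truth_coupled,
       latent = latent)
}

#' Simulate the genes x cells count matrix
#'
#' Gene means are log-normal; counts are negative-binomial with dispersion
#' `nb_dispersion` around `libsize x mean`; planted DEGs multiply the group-1
#' mean by `2^(+/- deg_log2fc)` with alternating sign; mitochondrial genes
#' follow the same law with means scaled so their expected count share equals
#' `mito_fraction`. When `methylomes` is supplied and coupled pairs were
#' planted, the group-1 mean of each coupled gene decreases log-linearly in
#' that cell's latent promoter methylation (negative coupling); group 2 is
#' left uncoupled.
#'
#' @param config a [sim_config()]
#' @param annotation result of [make_annotation()]
#' @param methylomes optional result of [simulate_methylomes()] (for coupling)
#' @return `list(counts, groups, truth)`: integer matrix, cell table, and
#'   planted-DEG truth table
#' @export
simulate_expression <- function(config, annotation, methylomes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "expression"))
  genes <- annotation$genes
  G <- nrow(genes)
  n <- config$n_cells_per_group
  cell_ids <- c(sprintf("g1_cell%02d", seq_len(n)),
                sprintf("g2_cell%02d", seq_len(n)))
  group <- rep(c(1L, 2L), each = n)
  if (config$n_outlier_mito > 0L) {
    cell_ids <- c(cell_ids, sprintf("g1_outlier_mito%02d",
                                    seq_len(config$n_outlier_mito)))
    group <- c(group, rep(1L, config$n_outlier_mito))
  }
  if (config$n_outlier_small > 0L) {
    cell_ids <- c(cell_ids, sprintf("g1_outlier_small%02d",
                                    seq_len(config$n_outlier_small)))
    group <- c(group, rep(1L, config$n_outlier_small))
  }
  C <- length(cell_ids)

  m <- exp(rnorm(G, config$expression_meanlog, config$expression_sdlog))
  # scale mito means to the target expected count share
  mito <- genes$is_mito
  if (any(mito) && config$mito_fraction > 0) {
    s_other <- sum(m[!mito])
    m[mito] <- config$mito_fraction / (1 - config$mito_fraction) *
      s_other / sum(mito)
  }

  truth <- data.table(gene_id = character(), log2fc = numeric())
  fc1 <- rep(1, G)
  if (config$n_degs_planted > 0L) {
    cand <- which(!mito)
    if (length(cand) < config$n_degs_planted) stop("not enough genes to plant DEGs")
    deg <- sample(cand, config$n_degs_planted)
    sgn <- rep(c(1, -1), length.out = length(deg))
    fc1[deg] <- 2^(sgn * config$deg_log2fc)
    truth <- data.table(gene_id = genes$gene_id[deg],
                        log2fc = sgn * config$deg_log2fc)
  }

  lib <- exp(rnorm(C, 0, config$libsize_lognormal_sigma))
  lib <- lib / exp(mean(log(lib)))

  # per-cell expected means (genes x cells)
  mu <- outer(m, lib)
  mu[, group == 1L] <- mu[, group == 1L] * fc1

  if (!is.null(methylomes) && nrow(methylomes$truth_coupled) > 0L) {
    cp <- methylomes$truth_coupled
    lat <- methylomes$latent
    for (k in seq_len(nrow(cp))) {
      gi <- match(cp$gene_id[k], genes$gene_id)
      ui <- paste0("cpl_", cp$region_id[k])
      frac <- lat[ui, match(cell_ids, colnames(lat))]
      g1 <- which(group == 1L & !is.na(frac))
      mu[gi, g1] <- mu[gi, g1] *
        exp(config$coupling_slope * (0.5 - frac[g1]))
    }
  }

  # planted RNA outliers: high-mito or tiny-library profiles
  himito <- grepl("outlier_mito", cell_ids)
  if (any(himito) && any(mito)) {
    # boost mito genes so their share lands near 20%
    boost <- 0.20 / max(config$mito_fraction, 1e-3)
    mu[mito, himito] <- mu[mito, himito] * boost
  }
  small <- grepl("outlier_small", cell_ids)
  if (any(small)) mu[, small] <- mu[, small] * 0.01

  size <- if (config$nb_dispersion > 1e-8) 1 / config$nb_dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) rnbinom(G * C, mu = as.vector(mu), size = size)
    else rpois(G * C, as.vector(mu)),
    nrow = G, dimnames = list(genes$gene_id, cell_ids)
  )
  storage.mode(counts) <- "integer"

  list(counts = counts,
       groups = data.table(cell_id = cell_ids, group = group,
                           planted_outlier = grepl("outlier", cell_ids)),
       truth = truth)
}

#' Generate a complete synthetic dataset, optionally writing it to disk
#'
#' Orchestrates [make_annotation()], [simulate_methylomes()] and
#' [simulate_expression()] under one seed. When `out_dir` is given, writes
#' per-cell `.cov.gz` files, per-class BED files, the gene table, the count
#' matrix, group assignments and truth tables in exactly the formats the
#' package readers accept.
#'
#' @param config a [sim_config()]
#' @param out_dir optional output directory
#' @return a list with `annotation`, `meth`, `expr` and, when written,
#'   `paths`
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  annotation <- make_annotation(config)
  meth <- simulate_methylomes(config, annotation)
  expr <- simulate_expression(config, annotation, meth)
  res <- list(annotation = annotation, meth = meth, expr = expr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    meth_dir <- file.path(out_dir, "methylomes")
    dir.create(meth_dir, showWarnings = FALSE)
    for (cid in names(meth$cells)) {
      p <- file.path(meth_dir, paste0(cid, ".cov.gz"))
      write_bismark_cov(meth$cells[[cid]], p)
    }
    paths$methylomes <- meth_dir
    for (cl in unique(annotation$regions$feature_class)) {
      p <- file.path(out_dir, paste0(cl, ".bed"))
      write_bed(annotation$regions[feature_class == cl], p)
      paths[[paste0("bed_", cl)]] <- p
    }
    paths$genes <- file.path(out_dir, "genes.tsv")
    write_gene_table(annotation$genes, paths$genes)
    paths$counts <- file.path(out_dir, "counts.tsv")
    write_count_matrix(expr$counts, paths$counts)
    paths$genome <- file.path(out_dir, "genome.tsv")
    fwrite(data.table(chrom = names(annotation$genome),
                      length = as.integer(annotation$genome)),
           paths$genome, sep = "\t")
    paths$groups_meth <- file.path(out_dir, "groups_meth.tsv")
    write_results_table(meth$groups, paths$groups_meth)
    paths$groups_rna <- file.path(out_dir, "groups_rna.tsv")
    write_results_table(expr$groups, paths$groups_rna)
    paths$truth_dmr <- file.path(out_dir, "truth_dmr.tsv")
    write_results_table(meth$truth, paths$truth_dmr)
    paths$truth_deg <- file.path(out_dir, "truth_deg.tsv")
    write_results_table(expr$truth, paths$truth_deg)
    res$paths <- paths
  }
  res
}
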
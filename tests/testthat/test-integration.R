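block_data <- function(n = 20, seed = 1) {
  set.seed(seed)
  g <- rep(1:2, each = n / 2)
  Xr <- matrix(0.1 * runif(40 * n), 40, n)
  Xm <- matrix(0.1 * runif(30 * n), 30, n)
  Xr[1:20, g == 1] <- Xr[1:20, g == 1] + 5
  Xr[21:40, g == 2] <- Xr[21:40, g == 2] + 5
  Xm[1:15, g == 1] <- Xm[1:15, g == 1] + 1
  Xm[16:30, g == 2] <- Xm[16:30, g == 2] + 1
  colnames(Xr) <- colnames(Xm) <- paste0("c", seq_len(n))
  rownames(Xr) <- paste0("g", 1:40)
  rownames(Xm) <- paste0("l", 1:30)
  list(Xr = Xr, Xm = Xm, g = g)
}

test_that("joint NMF recovers block structure with monotone objective", {
  d <- block_data()
  m <- joint_nmf(d$Xr, d$Xm, K = 2, seed = 7)
  expect_equal(mclust::adjustedRandIndex(m$factor_assignment, d$g), 1)
  expect_true(all(diff(m$objective_trace) <= 1e-8))
  expect_lt(tail(m$objective_trace, 1), m$objective_trace[1])
  expect_true(all(m$H >= 0) && all(m$W_rna >= 0) && all(m$W_meth >= 0))

  # same seed: identical; different seed: same partition up to labels
  m2 <- joint_nmf(d$Xr, d$Xm, K = 2, seed = 7)
  expect_identical(m$H, m2$H)
  m3 <- joint_nmf(d$Xr, d$Xm, K = 2, seed = 99)
  expect_equal(mclust::adjustedRandIndex(m3$factor_assignment,
                                         m$factor_assignment), 1)
})

test_that("lambda = 0 decouples the factorization from methylation", {
  d <- block_data(seed = 2)
  m0 <- joint_nmf(d$Xr, d$Xm, K = 2, lambda = 0, seed = 5)
  perm <- sample(nrow(d$Xm))
  m0b <- joint_nmf(d$Xr, d$Xm[perm, ], K = 2, lambda = 0, seed = 5)
  expect_identical(m0$H, m0b$H)   # H blind to the methylation layer
  expect_identical(m0$W_rna, m0b$W_rna)
})

test_that("joint NMF validates its inputs", {
  d <- block_data()
  expect_error(joint_nmf(d$Xr, d$Xm[, 1:10], K = 2), "cell sets differ|missing")
  expect_error(joint_nmf(d$Xr, d$Xm, K = 50), "cannot exceed")
  neg <- d$Xm; neg[1, 1] <- -1
  expect_error(joint_nmf(d$Xr, neg, K = 2), "non-negative")
  na <- d$Xm; na[1, 1] <- NA
  expect_error(joint_nmf(d$Xr, na, K = 2), "impute")
})

test_that("mean imputation fills gaps and drops all-missing regions", {
  frac <- rbind(a = c(0.2, NA, 0.4, 0.6), b = rep(NA_real_, 4))
  rmm <- make_rmm(frac)
  x <- impute_region_means(rmm)
  expect_equal(nrow(x), 1L)
  expect_equal(x["a", 2], mean(c(0.2, 0.4, 0.6)))
})

test_that("factor markers retain only strong one-sided features", {
  d <- block_data(seed = 3)
  m <- joint_nmf(d$Xr, d$Xm, K = 2, seed = 7)
  mk <- rank_factor_markers(m, d$Xr)
  expect_gt(nrow(mk), 0)
  # features active in the factor-1 block mark the factor of group-1 cells
  f1 <- m$factor_assignment[d$g == 1][1]
  top1 <- mk[factor == f1][rank == 1]$feature_id
  expect_true(top1 %in% paste0("g", 1:20))
  # constant feature is never a marker
  flat <- d$Xr; flat["g1", ] <- 1
  mk2 <- rank_factor_markers(m, flat)
  expect_false("g1" %in% mk2$feature_id)
  # permissive thresholds retain every feature with positive lfc
  mk3 <- rank_factor_markers(m, d$Xr, alpha = 1, min_fc = 0)
  expect_true(all(mk3$p_value <= 1))
  expect_gte(nrow(mk3), nrow(mk))
})

test_that("Pearson correlation matches brute force and thresholds gate pairs", {
  # affine decreasing relation in group 1; unrelated noise in group 2
  set.seed(41)
  n <- 8
  meth <- matrix(seq(0.1, 0.8, length.out = n), 1, n,
                 dimnames = list("r01", paste0("c", 1:n)))
  expr <- matrix(10 - 5 * meth[1, ], 1, n,
                 dimnames = list("gene_chr1_001", paste0("c", 1:n)))
  expr[1, 5:8] <- 5 + rnorm(4, 0, 0.3)   # group 2 decoupled
  regions <- data.table(chrom = "chr1", start = 0L, end = 1000L,
                        feature_class = "promoter", region_id = "r01")
  rmm <- make_rmm(meth, regions = regions)
  genes <- data.table(gene_id = "gene_chr1_001", chrom = "chr1",
                      strand = "+", tss = 500L, gene_start = 400L,
                      gene_end = 2000L, is_mito = FALSE)
  groups <- data.table(cell_id = paste0("c", 1:n), group = rep(1:2, each = 4))
  out <- correlate_meth_expr(rmm, expr, genes, groups, min_pairs = 4)
  g1rec <- out$records[group == 1]
  expect_equal(nrow(g1rec), 1L)
  expect_equal(g1rec$sign, "negative")
  expect_equal(g1rec$r, -1, tolerance = 1e-12)

  # brute-force covariance check on random vectors
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    r_brute <- mean((x - mean(x)) * (y - mean(y))) / (length(x) - 1) *
      length(x) / (sd(x) * sd(y))
    expect_equal(unname(cor(x, y)), r_brute, tolerance = 1e-12)
  }

  # different chromosome -> never a candidate pair
  genes_far <- copy(genes)[, chrom := "chr9"]
  out2 <- correlate_meth_expr(rmm, expr, genes_far, groups, min_pairs = 4)
  expect_equal(nrow(out2$records), 0L)
})

test_that("the difference-of-correlation clause rejects shared correlations", {
  # both groups correlate ~ equally: |r_g - r_other| <= 0.1 -> rejected
  set.seed(10)
  n <- 20
  z <- rnorm(n)
  meth <- matrix(0.5 + 0.1 * z + rnorm(n, 0, 0.001), 1, n,
                 dimnames = list("r01", paste0("c", 1:n)))
  expr <- matrix(5 + 2 * z + rnorm(n, 0, 0.001), 1, n,
                 dimnames = list("gene_chr1_001", paste0("c", 1:n)))
  regions <- data.table(chrom = "chr1", start = 0L, end = 1000L,
                        feature_class = "promoter", region_id = "r01")
  rmm <- make_rmm(meth, regions = regions)
  genes <- data.table(gene_id = "gene_chr1_001", chrom = "chr1",
                      strand = "+", tss = 500L, gene_start = 400L,
                      gene_end = 2000L, is_mito = FALSE)
  groups <- data.table(cell_id = paste0("c", 1:n),
                       group = rep(1:2, each = n / 2))
  out <- correlate_meth_expr(rmm, expr, genes, groups, min_pairs = 5)
  expect_equal(nrow(out$records), 0L)
})

test_that("planted promoter-expression coupling is recovered in group 1 only", {
  recovered <- 0; total <- 0; wrong_group <- 0
  for (s in 1:2) {
    cfg <- sim_config(seed = s, n_chrom = 2, chrom_length = 400000L,
                      n_genes = 40L, n_cgis = 20L, n_coupled_pairs = 8L,
                      coupling_slope = 6, coverage_mean = 20,
                      cpg_capture_rate = 0.5, bb_dispersion = 0.25)
    sim <- simulate_dataset(cfg)
    proms <- promoter_regions(sim$annotation$genes, sim$annotation$genome)
    rmm <- aggregate_region(sim$meth$cells, proms, min_cov_per_cpg = 5)
    sf <- size_factors(sim$expr$counts)
    expr <- log1p(sweep(sim$expr$counts, 2, sf, "/"))
    out <- correlate_meth_expr(rmm, expr, sim$annotation$genes,
                               sim$meth$groups)
    tc <- sim$meth$truth_coupled
    rec <- out$records
    for (i in seq_len(nrow(tc))) {
      total <- total + 1
      hit1 <- rec[locus_id == tc$region_id[i] & gene_id == tc$gene_id[i] &
                    group == 1 & sign == "negative"]
      hit2 <- rec[locus_id == tc$region_id[i] & gene_id == tc$gene_id[i] &
                    group == 2]
      if (nrow(hit1) > 0) recovered <- recovered + 1
      if (nrow(hit2) > 0) wrong_group <- wrong_group + 1
    }
  }
  expect_gte(recovered / total, 0.9)
  expect_lte(wrong_group / total, 0.2)
})
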
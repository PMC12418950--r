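test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L,  10L, 20L, 30L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # doubling one cell: factors (1/sqrt(2), sqrt(2))
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # single cell -> factor 1
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)

  # invariant to gene order
  set.seed(3)
  m3 <- matrix(rpois(300, 20), 30, 10,
               dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  expect_equal(size_factors(m3), size_factors(m3[sample(30), ]))

  # no gene expressed everywhere -> library-size fallback with warning
  m4 <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_warning(f <- size_factors(m4), "library-size")
  expect_equal(unname(f), c(1, 1))
})

test_that("HVG selection prefers varying genes with deterministic ties", {
  set.seed(4)
  counts <- rbind(
    flat = rep(50L, 20),
    bimodal = rep(c(5L, 200L), 10),
    alt = rep(c(10L, 11L), 10)
  )
  colnames(counts) <- paste0("c", 1:20)
  expect_equal(select_hvg(counts, 1, sf = rep(1, 20)), "bimodal")
  expect_setequal(select_hvg(counts, 3, sf = rep(1, 20)), rownames(counts))
  expect_warning(all_g <- select_hvg(counts, 10, sf = rep(1, 20)), "all genes")
  expect_equal(length(all_g), 3L)
})

test_that("nb_test log2fc uses the pseudocount formula", {
  set.seed(5)
  groups <- two_group_table(10)
  counts <- matrix(rpois(20, 25), 1, 20,
                   dimnames = list("g1", groups$cell_id))
  res <- nb_test(counts, groups, sf = setNames(rep(1, 20), groups$cell_id))
  m1 <- mean(counts[1, 1:10]); m2 <- mean(counts[1, 11:20])
  expect_equal(res$log2fc, log2((m1 + 0.5) / (m2 + 0.5)), tolerance = 1e-12)

  # spec arithmetic: means 40 vs 10 -> log2(40.5/10.5)
  expect_equal(log2((40 + 0.5) / (10 + 0.5)), 1.9475, tolerance = 1e-4)
})

test_that("swapping group labels negates log2fc and swaps up/down", {
  cfg <- sim_config(seed = 19, n_chrom = 2, chrom_length = 500000L,
                    n_genes = 50L, n_cgis = 0L, n_transposons = 0L,
                    n_imprinted = 0L, n_degs_planted = 10L)
  ann <- make_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  g <- ex$groups
  g_swapped <- copy(g)[, group := 3L - group]
  a <- de_analysis(ex$counts, g)
  b <- de_analysis(ex$counts, g_swapped)
  expect_equal(a$results$log2fc, -b$results$log2fc, tolerance = 1e-12)
  expect_equal(unname(a$summary["n_up"]), unname(b$summary["n_down"]))
  expect_equal(a$results$p_value, b$results$p_value, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # missing p excluded from m and propagated
  expect_equal(bh_fdr(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DEG labels honour both FDR and fold-change thresholds", {
  res <- data.table(
    gene_id = c("a", "b", "c", "d"),
    base_mean = 10, log2fc = c(2.5, 1.9, 5, -2.5), se = 1, t_stat = 1,
    p_value = c(0.001, 0.001, 0.06, 0.001), dispersion = 0.1
  )
  out <- call_degs(copy(res)[, fdr := p_value])
  expect_equal(out$results$direction, c("up", "ns", "ns", "down"))
  expect_equal(unname(out$summary), c(1L, 1L, 2L), ignore_attr = TRUE)
})

test_that("null NB p-values are uniform and dispersion limit matches Poisson", {
  cfg <- sim_config(seed = 23, n_chrom = 2, chrom_length = 10000000L,
                    n_genes = 2000L, n_cgis = 0L, n_transposons = 0L,
                    n_imprinted = 0L)
  ann <- make_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  res <- nb_test(ex$counts, ex$groups)
  p <- res$p_value[!is.na(res$p_value)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)

  # near-zero dispersion, large counts: Wald p close to a Poisson GLM Wald p
  set.seed(7)
  groups <- two_group_table(20)
  counts <- matrix(rpois(40 * 50, 100), 50, 40,
                   dimnames = list(paste0("g", 1:50), groups$cell_id))
  res2 <- nb_test(counts, groups, sf = setNames(rep(1, 40), groups$cell_id),
                  pc = 0, shrink_weight = 1)
  gfac <- factor(groups$group)
  for (i in seq(1, 50, by = 10)) {
    fit <- summary(stats::glm(counts[i, ] ~ gfac, family = stats::poisson))
    p_pois <- fit$coefficients[2, 4]
    if (p_pois > 1e-6) {
      expect_lt(abs(log(res2$p_value[i]) - log(p_pois)), log(2))
    }
  }
})

test_that("planted DEGs are recovered at the stringent thresholds", {
  cfg <- sim_config(seed = 29, n_chrom = 2, chrom_length = 10000000L,
                    n_genes = 2000L, n_cgis = 0L, n_transposons = 0L,
                    n_imprinted = 0L, n_degs_planted = 100L, deg_log2fc = 2.5)
  ann <- make_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  de <- de_analysis(ex$counts, ex$groups)
  called <- de$results[direction != "ns"]
  sens <- mean(ex$truth$gene_id %in% called$gene_id)
  expect_gte(sens, 0.8)
  if (nrow(called) > 0) {
    expect_lte(mean(!called$gene_id %in% ex$truth$gene_id), 0.1)
  }
  # direction agrees with the planted sign among true positives
  tp <- called[gene_id %in% ex$truth$gene_id]
  planted_sign <- sign(ex$truth$log2fc[match(tp$gene_id, ex$truth$gene_id)])
  expect_true(all(sign(tp$log2fc) == planted_sign))
})

test_that("PCA embedding is deterministic and separates planted groups", {
  # centered rank-1 matrix: PC1 explains everything
  x <- outer(c(1, 2, 3, 4), c(1, -1, 2, -2, 0.5))
  counts <- round(100 + 10 * x)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("g", 1:4), paste0("c", 1:5))
  # duplicated cell gives identical score rows
  counts2 <- cbind(counts, c6 = counts[, 1])
  emb <- pca_embed(counts2, n_components = 2, sf = setNames(rep(1, 6),
                                                            colnames(counts2)))
  expect_equal(emb$scores["c1", ], emb$scores["c6", ], tolerance = 1e-10)

  expect_error(pca_embed(counts, n_components = 10), "n_components")

  cfg <- sim_config(seed = 31, n_chrom = 2, chrom_length = 500000L,
                    n_genes = 50L, n_cgis = 0L, n_transposons = 0L,
                    n_imprinted = 0L, n_degs_planted = 20L, deg_log2fc = 3)
  ann <- make_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  emb2 <- pca_embed(ex$counts, n_components = 2)
  g <- ex$groups$group
  s1 <- emb2$scores[, 1]
  # groups linearly separable on PC1: silhouette-style separation
  gap <- abs(mean(s1[g == 1]) - mean(s1[g == 2]))
  spread <- max(sd(s1[g == 1]), sd(s1[g == 2]))
  expect_gt(gap / (gap + spread), 0.5)
})
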
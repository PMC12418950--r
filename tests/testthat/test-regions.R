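test_that("window tiling covers chromosomes with a short last window", {
  w <- tile_windows(c(chrA = 2500), 1000)
  expect_equal(w$start, c(0L, 1000L, 2000L))
  expect_equal(w$end, c(1000L, 2000L, 2500L))
  expect_equal(nrow(tile_windows(c(chrA = 1000), 1000)), 1L)
  huge <- tile_windows(c(chrA = 700), 1e9)
  expect_equal(huge$end, 700L)
  expect_error(tile_windows(c(chrA = 100), 0), "width")
})

test_that("region aggregation pools reads and honours the coverage floor", {
  cells <- list(
    c1 = calls_dt("chr1", c(10, 20), c(3, 2), c(1, 2))  # cov 4 and 4
  )
  reg <- data.table(chrom = "chr1", start = 0L, end = 100L,
                    feature_class = "CGI", region_id = "r1")
  low <- aggregate_region(cells, reg, min_cov_per_cpg = 1)
  expect_equal(low$meth_fraction[1, 1], 5 / 8)      # pooled (3+2)/(4+4)
  expect_equal(low$n_cpgs_covered[1, 1], 2L)
  expect_equal(low$total_reads[1, 1], 8L)

  # per-CpG mean pooling alternative
  cm <- aggregate_region(cells, reg, min_cov_per_cpg = 1,
                         pooling = "cpg_mean")
  expect_equal(cm$meth_fraction[1, 1], mean(c(3 / 4, 2 / 4)))

  # neither site reaches 5 reads -> missing with zero coverage
  high <- aggregate_region(cells, reg, min_cov_per_cpg = 5)
  expect_true(is.na(high$meth_fraction[1, 1]))
  expect_equal(high$n_cpgs_covered[1, 1], 0L)

  # region without CpGs -> missing
  reg2 <- rbind(reg, data.table(chrom = "chr1", start = 200L, end = 300L,
                                feature_class = "CGI", region_id = "r2"))
  out <- aggregate_region(cells, reg2, min_cov_per_cpg = 1)
  expect_true(is.na(out$meth_fraction["r2", 1]))
  expect_error(aggregate_region(cells, reg[0], 1), "empty region")
})

test_that("membership is half-open; boundary CpGs belong to one window only", {
  cells <- list(c1 = calls_dt("chr1", c(0, 999, 1000), c(1, 1, 1), c(0, 0, 0)))
  w <- tile_windows(c(chr1 = 2000), 1000)
  x <- aggregate_region(cells, w, min_cov_per_cpg = 1)
  expect_equal(x$n_cpgs_covered[, 1], c(2L, 1L), ignore_attr = TRUE)
})

test_that("windows conserve qualifying reads and reproduce global methylation", {
  cfg <- sim_config(seed = 13, n_chrom = 2, chrom_length = 150000L,
                    n_genes = 10L, n_cgis = 6L, n_imprinted = 0L, n_mito_genes = 2L,
                    n_transposons = 4L)
  sim <- simulate_dataset(cfg)
  cells <- sim$meth$cells[1:4]
  w <- tile_windows(sim$annotation$genome, 1000)
  x <- aggregate_region(cells, w, min_cov_per_cpg = 1)
  for (j in seq_along(cells)) {
    expect_equal(sum(x$total_reads[, j]),
                 sum(cells[[j]]$n_meth + cells[[j]]$n_unmeth))
  }
  # a whole-chromosome region at min_cov 1 reproduces global methylation
  whole <- data.table(chrom = names(sim$annotation$genome),
                      start = 0L,
                      end = as.integer(sim$annotation$genome),
                      feature_class = "window1kb",
                      region_id = names(sim$annotation$genome))
  g <- aggregate_region(cells, whole, min_cov_per_cpg = 1)
  qc <- bs_cell_qc(cells)
  pooled <- colSums(g$meth_fraction * g$total_reads, na.rm = TRUE) /
    colSums(g$total_reads)
  expect_equal(100 * unname(pooled), qc$global_meth_pct, tolerance = 1e-12)
})

test_that("VMR detection ranks by variance and merges adjacent windows", {
  # 10 windows x 8 cells: window 3 and 4 bimodal (adjacent), window 7 bimodal
  set.seed(2)
  frac <- matrix(0.5 + rnorm(80, 0, 0.01), 10, 8)
  bim <- rep(c(0.02, 0.98), each = 4)
  frac[3, ] <- bim; frac[4, ] <- bim; frac[7, ] <- rev(bim)
  rmm <- make_rmm(frac, feature_class = "window1kb")
  v <- detect_vmrs(rmm, top_fraction = 0.3, min_cells = 4)
  # closed-form sample variance of the bimodal pattern
  expect_equal(max(v$variance), var(bim))
  expect_equal(var(bim), 0.25 * (0.96^2) * 8 / 7, tolerance = 1e-12)
  # adjacent windows 3-4 merged into one VMR spanning 2 kb
  top <- v[1]
  expect_equal(top$end - top$start, 2000L)
  expect_equal(nrow(v), 2L)

  # identical fractions across cells are never selected
  flat <- make_rmm(matrix(0.4, 5, 8), feature_class = "window1kb")
  expect_warning(v0 <- detect_vmrs(flat, top_fraction = 0.5, min_cells = 9),
                 "no eligible")
  expect_equal(nrow(v0), 0L)
})

test_that("VMR detection is invariant to cell and chromosome order", {
  cfg <- sim_config(seed = 17, n_chrom = 2, chrom_length = 100000L,
                    n_genes = 8L, n_cgis = 4L, n_imprinted = 0L, n_mito_genes = 2L,
                    n_transposons = 4L)
  sim <- simulate_dataset(cfg)
  w <- tile_windows(sim$annotation$genome, 1000)
  x1 <- aggregate_region(sim$meth$cells, w, min_cov_per_cpg = 1)
  perm <- rev(seq_along(sim$meth$cells))
  x2 <- aggregate_region(sim$meth$cells[perm], w, min_cov_per_cpg = 1)
  w_rev <- w[order(-match(chrom, unique(chrom)), start)]
  x3 <- aggregate_region(sim$meth$cells, w_rev, min_cov_per_cpg = 1)
  v1 <- detect_vmrs(x1, 0.05)
  v2 <- detect_vmrs(x2, 0.05)
  v3 <- detect_vmrs(x3, 0.05)
  key <- function(v) v[order(chrom, start), .(chrom, start, end, variance)]
  expect_equal(key(v1), key(v2))
  expect_equal(key(v1), key(v3))
})

test_that("planted bimodal windows are recovered at matched top fraction", {
  set.seed(31)
  n_win <- 200; n_cells <- 16
  frac <- matrix(rbeta(n_win * n_cells, 10, 10), n_win, n_cells)
  planted <- sample(n_win, 10)
  for (i in planted) {
    frac[i, ] <- sample(rep(c(0.02, 0.98), each = n_cells / 2))
  }
  # non-adjacent planted windows so recall is countable per window
  regions <- data.table(chrom = "chr1",
                        start = (seq_len(n_win) - 1L) * 2000L,
                        end = (seq_len(n_win) - 1L) * 2000L + 1000L,
                        feature_class = "window1kb",
                        region_id = sprintf("w%03d", seq_len(n_win)))
  rmm <- make_rmm(frac, regions = regions)
  v <- detect_vmrs(rmm, top_fraction = 10 / n_win)
  hit <- sum(v$start %in% regions$start[planted])
  expect_gte(hit / 10, 0.9)
})

test_that("imprint report flags drifting regions and honours tolerance", {
  frac <- rbind(r1 = rep(0.93, 8), r2 = c(rep(0.9, 4), rep(0.4, 4)))
  rmm <- make_rmm(frac, feature_class = "imprinted_gDMR")
  groups <- two_group_table(4)
  rep_ <- imprint_report(rmm, groups)
  expect_true(rep_[region_id == "r1"]$appropriate)
  expect_false(rep_[region_id == "r2"]$appropriate)
  expect_equal(rep_[region_id == "r2"]$difference, 0.5)
  # empty input
  none <- make_rmm(frac[0, , drop = FALSE], feature_class = "CGI")
  expect_equal(nrow(imprint_report(none, groups)), 0L)
})
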
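#' Configuration for the differential-methylation filter cascade and test
#'
#' The three-rule cascade: (1) per-site coverage of at least
#' `min_cov_per_cpg` reads (applied upstream, in [aggregate_region()]);
#' (2) at least half the cells of each group must have reads in the region;
#' (3) the average region read count over contributing cells must exceed
#' `min_mean_reads_per_group` in each group. A region is then a DMR when its
#' two-sided t-test p-value is below `alpha` and the absolute group
#' difference in methylation fraction exceeds `min_delta` (10 percentage
#' points by default). Group methylation levels above `hyper_threshold` /
#' below `hypo_threshold` are labelled hyper-/hypomethylated.
#'
#' @param min_cov_per_cpg rule-1 per-site coverage floor (default 5)
#' @param min_cell_fraction_per_group rule-2 fraction (default 0.5)
#' @param min_mean_reads_per_group rule-3 strict lower bound (default 10)
#' @param alpha significance level (default 0.05, deliberately uncorrected —
#'   the convention of this filter-cascade procedure; see `adjust`)
#' @param min_delta minimum |group difference| in methylation fraction
#' @param hyper_threshold,hypo_threshold level labels (default 0.75 / 0.25)
#' @param test_variant `"welch"` (the default of R's `t.test`) or `"student"`
#' @param rule3_metric `"region_reads"` (mean over contributing cells of the
#'   region's qualifying read total) or `"per_cpg"` (mean per-CpG coverage)
#' @param adjust optional p-value adjustment, `"none"` (default) or `"BH"`
#' @return a `dm_filter_config` list
#' @export
dm_filter_config <- function(min_cov_per_cpg = 5,
                             min_cell_fraction_per_group = 0.5,
                             min_mean_reads_per_group = 10,
                             alpha = 0.05,
                             min_delta = 0.1,
                             hyper_threshold = 0.75,
                             hypo_threshold = 0.25,
                             test_variant = c("welch", "student"),
                             rule3_metric = c("region_reads", "per_cpg"),
                             adjust = c("none", "BH")) {
  cfg <- list(
    min_cov_per_cpg = min_cov_per_cpg,
    min_cell_fraction_per_group = min_cell_fraction_per_group,
    min_mean_reads_per_group = min_mean_reads_per_group,
    alpha = alpha, min_delta = min_delta,
    hyper_threshold = hyper_threshold, hypo_threshold = hypo_threshold,
    test_variant = match.arg(test_variant),
    rule3_metric = match.arg(rule3_metric),
    adjust = match.arg(adjust)
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)")
  if (cfg$hypo_threshold >= cfg$hyper_threshold) {
    stop("hypo_threshold must be below hyper_threshold")
  }
  class(cfg) <- "dm_filter_config"
  cfg
}

.two_group_index <- function(matrix_, groups) {
  g <- groups$group[match(matrix_$cell_ids, groups$cell_id)]
  if (any(is.na(g))) {
    stop("cells missing from the group table: ",
         paste(matrix_$cell_ids[is.na(g)], collapse = ", "))
  }
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("exactly two groups required, got ", length(lv))
  list(g1 = which(g == lv[1]), g2 = which(g == lv[2]), levels = lv)
}

#' Apply the region filter cascade (rules 2 and 3)
#'
#' Rule 2: a region is retained only if at least
#' `ceil(min_cell_fraction_per_group x group size)` cells of *each* group
#' have reads in the region. Rule 3 (evaluated after rule 2): the mean read
#' count over contributing cells must be strictly greater than
#' `min_mean_reads_per_group` in each group. Per-rule drop counts are
#' reported in cascade order.
#'
#' @param matrix_ a `region_meth` (built with rule 1 already applied via
#'   `min_cov_per_cpg` in [aggregate_region()])
#' @param groups table with `cell_id` and `group` (exactly two levels)
#' @param cfg a [dm_filter_config()]
#' @return `list(retained, drops)`: logical vector over regions, and a named
#'   drop-count vector `c(rule2, rule3)`
#' @export
dm_filter_cascade <- function(matrix_, groups, cfg = dm_filter_config()) {
  idx <- .two_group_index(matrix_, groups)
  obs <- !is.na(matrix_$meth_fraction)
  n1 <- rowSums(obs[, idx$g1, drop = FALSE])
  n2 <- rowSums(obs[, idx$g2, drop = FALSE])
  need1 <- ceiling(cfg$min_cell_fraction_per_group * length(idx$g1))
  need2 <- ceiling(cfg$min_cell_fraction_per_group * length(idx$g2))
  pass2 <- n1 >= need1 & n2 >= need2

  reads <- matrix_$total_reads
  if (cfg$rule3_metric == "per_cpg") {
    reads <- ifelse(matrix_$n_cpgs_covered > 0,
                    matrix_$total_reads / matrix_$n_cpgs_covered, 0)
  }
  mean_reads_group <- function(cols) {
    r <- reads[, cols, drop = FALSE]
    o <- obs[, cols, drop = FALSE]
    s <- rowSums(r * o)
    n <- rowSums(o)
    ifelse(n > 0, s / n, 0)
  }
  m1 <- mean_reads_group(idx$g1)
  m2 <- mean_reads_group(idx$g2)
  pass3 <- m1 > cfg$min_mean_reads_per_group &
    m2 > cfg$min_mean_reads_per_group

  retained <- pass2 & pass3
  drops <- c(rule2 = sum(!pass2), rule3 = sum(pass2 & !pass3))
  list(retained = retained, drops = drops)
}

#' Two-sample t-test on per-cell methylation fractions
#'
#' `variant = "welch"` is the unequal-variance test with Welch-Satterthwaite
#' degrees of freedom — the default behaviour of R's `t.test`, and therefore
#' what a plain `t.test` call computes; `variant = "student"` pools the variance
#' with `n1 + n2 - 2` df. Two-sided. Degenerate inputs are handled
#' explicitly: fewer than two values in either group is untestable (`NA`
#' with a reason); zero variance in both groups gives `p = 1` at equal means
#' and `p = 0` (t infinite) otherwise.
#'
#' @param fractions_g1,fractions_g2 numeric vectors (NAs dropped)
#' @param variant `"welch"` or `"student"`
#' @return `list(t_stat, p_value, reason)`; `reason` is `NA` when tested
#' @export
dm_test <- function(fractions_g1, fractions_g2,
                    variant = c("welch", "student")) {
  variant <- match.arg(variant)
  x <- fractions_g1[!is.na(fractions_g1)]
  y <- fractions_g2[!is.na(fractions_g2)]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(t_stat = NA_real_, p_value = NA_real_,
                reason = "fewer than 2 covered cells in a group"))
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_stat = 0, p_value = 1, reason = NA_character_))
    }
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                reason = NA_character_))
  }
  res <- t.test(x, y, var.equal = (variant == "student"))
  list(t_stat = unname(res$statistic), p_value = res$p.value,
       reason = NA_character_)
}

#' Call differentially methylated regions
#'
#' Runs the filter cascade, then per retained region computes group mean
#' methylation over contributing cells, their difference
#' (`delta = mean_g1 - mean_g2`), the two-sample test, significance
#' (`p < alpha` and `|delta| > min_delta`), and per-group level labels from
#' the 75/25 rule (mean above `hyper_threshold` is `hyper`, below
#' `hypo_threshold` is `hypo`, otherwise `intermediate`). Regions failing the
#' cascade are absent; retained regions that cannot be tested (a group with
#' fewer than two covered cells) appear with status `untested`.
#'
#' @param matrix_ a `region_meth`
#' @param groups table with `cell_id` and `group`
#' @param cfg a [dm_filter_config()]
#' @return a `data.table` of DMR results, one row per retained region
#' @export
call_dmrs <- function(matrix_, groups, cfg = dm_filter_config()) {
  idx <- .two_group_index(matrix_, groups)
  casc <- dm_filter_cascade(matrix_, groups, cfg)
  keep <- which(casc$retained)
  label <- function(m) {
    ifelse(is.na(m), NA_character_,
           ifelse(m > cfg$hyper_threshold, "hyper",
                  ifelse(m < cfg$hypo_threshold, "hypo", "intermediate")))
  }
  rows <- lapply(keep, function(i) {
    f1 <- matrix_$meth_fraction[i, idx$g1]
    f2 <- matrix_$meth_fraction[i, idx$g2]
    tt <- dm_test(f1, f2, cfg$test_variant)
    m1 <- mean(f1, na.rm = TRUE)
    m2 <- mean(f2, na.rm = TRUE)
    data.table(
      region_id = matrix_$regions$region_id[i],
      feature_class = matrix_$regions$feature_class[i],
      mean_g1 = m1, mean_g2 = m2, delta = m1 - m2,
      t_stat = tt$t_stat, p_value = tt$p_value,
      n_cells_g1 = sum(!is.na(f1)), n_cells_g2 = sum(!is.na(f2)),
      status = if (is.na(tt$p_value)) "untested" else "tested",
      reason = tt$reason
    )
  })
  if (length(rows) == 0L) {
    return(data.table(region_id = character(), feature_class = character(),
                      mean_g1 = numeric(), mean_g2 = numeric(),
                      delta = numeric(), t_stat = numeric(),
                      p_value = numeric(), n_cells_g1 = integer(),
                      n_cells_g2 = integer(), status = character(),
                      reason = character(), significant = logical(),
                      level_label_g1 = character(),
                      level_label_g2 = character()))
  }
  res <- data.table::rbindlist(rows)
  p_eff <- if (cfg$adjust == "BH") bh_fdr(res$p_value) else res$p_value
  res[, significant := !is.na(p_eff) & p_eff < cfg$alpha &
        abs(delta) > cfg$min_delta]
  res[, `:=`(level_label_g1 = label(mean_g1),
             level_label_g2 = label(mean_g2))]
  res[]
}

#' Summarise DMR calls per feature class
#'
#' Per feature class: regions tested, significant DMRs, hyper/hypo counts per
#' group among significant DMRs, and the percentage of hypomethylated regions
#' among the level-labelled DMRs of each group (integer percent, half-up) —
#' the quantity behind statements like "42 of 52 CGI DMRs (81%)
#' hypomethylated".
#'
#' @param results output of [call_dmrs()]
#' @return a `data.table`, one row per feature class
#' @export
summarize_dmrs <- function(results) {
  if (nrow(results) == 0L) {
    return(data.table(feature_class = character(), n_tested = integer(),
                      n_significant = integer(), n_hyper_g1 = integer(),
                      n_hypo_g1 = integer(), n_hyper_g2 = integer(),
                      n_hypo_g2 = integer(), pct_hypo_g1 = numeric(),
                      pct_hypo_g2 = numeric()))
  }
  results[, {
    sig <- significant %in% TRUE
    h1 <- sum(sig & level_label_g1 == "hyper", na.rm = TRUE)
    l1 <- sum(sig & level_label_g1 == "hypo", na.rm = TRUE)
    h2 <- sum(sig & level_label_g2 == "hyper", na.rm = TRUE)
    l2 <- sum(sig & level_label_g2 == "hypo", na.rm = TRUE)
    .(n_tested = sum(status == "tested"),
      n_significant = sum(sig),
      n_hyper_g1 = h1, n_hypo_g1 = l1,
      n_hyper_g2 = h2, n_hypo_g2 = l2,
      pct_hypo_g1 = hypo_percent(l1, h1),
      pct_hypo_g2 = hypo_percent(l2, h2))
  }, by = feature_class]
}

#' Percentage of hypomethylated regions among labelled DMRs
#'
#' `100 * n_hypo / (n_hypo + n_hyper)` rounded half-up to an integer percent;
#' `NA` when no region is labelled.
#'
#' @param n_hypo,n_hyper counts of hypo- and hypermethylated DMRs
#' @return integer percent
#' @export
hypo_percent <- function(n_hypo, n_hyper) {
  tot <- n_hypo + n_hyper
  if (tot == 0) return(NA_real_)
  round_half_up(100 * n_hypo / tot, 0)
}
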
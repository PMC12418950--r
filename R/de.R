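#' Median-of-ratios size factors
#'
#' Per-cell normalization constants: each cell's factor is the median over
#' genes of the ratio of its count to the gene's geometric mean across cells,
#' restricted to genes with a positive geometric mean (i.e. expressed in
#' every cell). Factors are rescaled to geometric mean 1. When no gene is
#' expressed in all cells the function falls back to library-size factors
#' with a warning.
#'
#' @param counts genes x cells matrix
#' @return named numeric vector of per-cell factors
#' @export
size_factors <- function(counts) {
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    warning("no gene expressed in every cell; using library-size factors")
    f <- colSums(counts)
    f <- f / exp(mean(log(f)))
    return(setNames(f, colnames(counts)))
  }
  f <- apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    exp(median(log(cnt) - loggeo[use]))
  })
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Select highly variable genes
#'
#' Genes are ranked by standardized variance: the variance of
#' `log1p(normalized count)` divided by a mean-variance trend fitted as a
#' rolling median over mean-expression bins. Ties break deterministically by
#' gene id. Constant genes have standardized variance 0.
#'
#' @param counts genes x cells matrix
#' @param n number of genes to select (default 2000)
#' @param sf optional size factors (computed if missing)
#' @param n_bins trend bins (default 20)
#' @return character vector of selected gene ids, highest variance first
#' @export
select_hvg <- function(counts, n = 2000, sf = NULL, n_bins = 20) {
  if (n > nrow(counts)) {
    warning("n exceeds the number of genes; returning all genes")
    n <- nrow(counts)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  l <- log1p(norm)
  mu <- rowMeans(norm)
  v <- apply(l, 1L, var)
  ord <- order(mu)
  # at least ~10 genes per trend bin so the rolling median is meaningful;
  # tiny panels collapse to a single global-median bin
  eff_bins <- max(1L, min(n_bins, length(ord) %/% 10L))
  bins <- if (eff_bins >= 2L) {
    cut(seq_along(ord), breaks = eff_bins, labels = FALSE)
  } else {
    rep(1L, length(ord))
  }
  trend_by_bin <- tapply(v[ord], bins, median)
  trend <- numeric(length(v))
  trend[ord] <- pmax(trend_by_bin[bins], 1e-12)
  std_var <- ifelse(v == 0, 0, v / trend)
  ids <- rownames(counts)
  sel <- order(-std_var, ids)[seq_len(n)]
  ids[sel]
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' A transparent from-scratch NB test: counts are size-factor normalized;
#' per-gene dispersion is estimated by method of moments from the pooled
#' within-group variance and shrunk toward a binned-median mean-dispersion
#' trend; the log2 fold change uses a pseudocount (`pc`, default 0.5) on the
#' group means (group 1 relative to group 2, group 2 the reference); the
#' Wald statistic divides the log2 fold change by a delta-method standard
#' error from the NB variance `mu + alpha mu^2`. Two-sided p-values use a t
#' reference with `n1 + n2 - 2` degrees of freedom, which absorbs the
#' dispersion-estimation noise at two-digit cell numbers. Genes with zero
#' counts everywhere are untested (`NA`).
#'
#' @param counts genes x cells matrix
#' @param groups table with `cell_id`, `group` (two levels; the higher level
#'   is the reference)
#' @param sf optional size factors
#' @param pc pseudocount on normalized means (default 0.5)
#' @param shrink_weight weight of the trend in the shrunk dispersion
#'   (default 0.7)
#' @return a `data.table` with `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `t_stat`, `p_value`, `dispersion`
#' @export
nb_test <- function(counts, groups, sf = NULL, pc = 0.5,
                    shrink_weight = 0.7) {
  g <- groups$group[match(colnames(counts), groups$cell_id)]
  if (any(is.na(g))) stop("cells missing from the group table")
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("exactly two groups required")
  i1 <- g == lv[1]; i2 <- g == lv[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 cells")
  if (is.null(sf)) sf <- size_factors(counts)
  y <- sweep(counts, 2L, sf, "/")

  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  v1 <- apply(y[, i1, drop = FALSE], 1L, var)
  v2 <- apply(y[, i2, drop = FALSE], 1L, var)
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  inv_sf <- mean(1 / sf)

  # method-of-moments dispersion: Var(y) ~ mu * mean(1/sf) + alpha mu^2
  alpha_raw <- ifelse(mu > 0, pmax(0, (vw - mu * inv_sf) / mu^2), NA_real_)
  expressed <- mu > 0
  # binned-median trend over log-mean, interpolated
  ord <- order(mu[expressed])
  idx_e <- which(expressed)[ord]
  nb <- min(15L, max(1L, floor(sum(expressed) / 20)))
  bins <- if (nb >= 2L) {
    cut(seq_along(idx_e), breaks = nb, labels = FALSE)
  } else {
    rep(1L, length(idx_e))
  }
  bin_med <- tapply(alpha_raw[idx_e], bins, median, na.rm = TRUE)
  bin_med[is.na(bin_med)] <- 0
  trend <- numeric(length(mu))
  trend[idx_e] <- bin_med[bins]
  alpha <- shrink_weight * trend + (1 - shrink_weight) * alpha_raw
  alpha <- pmax(alpha, 1e-8)

  log2fc <- log2((m1 + pc) / (m2 + pc))
  se_g <- function(m, n) {
    # Var(log2(mean + pc)) by the delta method
    vm <- (m * inv_sf + alpha * m^2) / n
    sqrt(vm) / ((m + pc) * log(2))
  }
  se <- sqrt(se_g(m1, n1)^2 + se_g(m2, n2)^2)
  t_stat <- ifelse(se > 0, log2fc / se, NA_real_)
  p <- 2 * pt(-abs(t_stat), df = n1 + n2 - 2)
  p[!expressed] <- NA_real_
  t_stat[!expressed] <- NA_real_
  data.table(
    gene_id = rownames(counts),
    base_mean = mu, log2fc = log2fc, se = se,
    t_stat = t_stat, p_value = p, dispersion = alpha
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotone enforcement; missing p-values are
#' excluded from the number of tests and propagated as missing.
#'
#' @param p_values numeric vector in `[0,1]`, NAs allowed
#' @return adjusted values, same length and order
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0,1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Label differentially expressed genes
#'
#' A gene is `up` when `fdr < alpha` and `log2fc >= lfc_min`, `down` when
#' `fdr < alpha` and `log2fc <= -lfc_min`, otherwise `ns`. Defaults are the
#' standard stringent thresholds (FDR < 0.05, |log2FC| >= 2).
#'
#' @param results output of [nb_test()] (an `fdr` column is added if absent)
#' @param alpha FDR threshold (default 0.05)
#' @param lfc_min minimum |log2 fold change| (default 2)
#' @return `list(results, summary)`: the annotated table with `fdr` and
#'   `direction`, and `c(n_up, n_down, n_total)`
#' @export
call_degs <- function(results, alpha = 0.05, lfc_min = 2) {
  res <- data.table::copy(as.data.table(results))
  if (!"fdr" %in% names(res)) res[, fdr := bh_fdr(p_value)]
  res[, direction := ifelse(
    is.na(fdr), "ns",
    ifelse(fdr < alpha & log2fc >= lfc_min, "up",
           ifelse(fdr < alpha & log2fc <= -lfc_min, "down", "ns")))]
  n_up <- sum(res$direction == "up")
  n_down <- sum(res$direction == "down")
  list(results = res[],
       summary = c(n_up = n_up, n_down = n_down, n_total = n_up + n_down))
}

#' Full two-group differential expression analysis
#'
#' Convenience wrapper: minimal expression prefilter (nonzero in at least
#' `min_cells` cells), size factors, NB Wald test, BH-FDR and DEG labelling.
#'
#' @param counts genes x cells matrix
#' @param groups table with `cell_id`, `group`
#' @param alpha,lfc_min DEG thresholds (defaults 0.05, 2)
#' @param min_cells minimal-expression prefilter (default 3)
#' @param ... passed to [nb_test()]
#' @return as [call_degs()], plus `n_genes_tested`
#' @export
de_analysis <- function(counts, groups, alpha = 0.05, lfc_min = 2,
                        min_cells = 3, ...) {
  keep <- rowSums(counts > 0) >= min_cells
  sf <- size_factors(counts)
  res <- nb_test(counts[keep, , drop = FALSE], groups, sf = sf, ...)
  out <- call_degs(res, alpha = alpha, lfc_min = lfc_min)
  out$n_genes_tested <- sum(keep)
  out
}

#' PCA embedding of cells
#'
#' Restricts to the given genes, log-normalizes, centers and unit-scales each
#' gene (constant genes dropped), and returns the top right-singular scores.
#' Sign convention: each component is flipped so its largest-|loading|
#' coordinate is positive, making scores deterministic.
#'
#' @param counts genes x cells matrix
#' @param hvg gene ids to use (default all)
#' @param n_components number of components (default 2)
#' @param sf optional size factors
#' @return `list(scores, loadings, var_explained)`; `scores` is cells x
#'   components
#' @export
pca_embed <- function(counts, hvg = rownames(counts), n_components = 2,
                      sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  x <- log1p(sweep(counts[hvg, , drop = FALSE], 2L, sf, "/"))
  keep <- apply(x, 1L, var) > 0
  x <- x[keep, , drop = FALSE]
  if (n_components > min(dim(x))) {
    stop("n_components exceeds the matrix rank bound")
  }
  xs <- t(scale(t(x)))  # genes centered/scaled; columns = cells
  sv <- svd(t(xs), nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  for (k in seq_len(n_components)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- colnames(counts)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings,
       var_explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2))
}
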
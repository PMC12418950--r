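library(data.table)

# small calls table constructor (internal 0-based positions)
calls_dt <- function(chrom, pos, n_meth, n_unmeth) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth))
  data.table::setkey(dt, chrom, pos)
  dt[]
}

# a region_meth built directly from a fraction matrix (for caller tests);
# reads defaults to full observation with the given per-cell read count
make_rmm <- function(frac, reads_per_cell = 20, regions = NULL,
                     feature_class = "CGI") {
  R <- nrow(frac); C <- ncol(frac)
  if (is.null(rownames(frac))) rownames(frac) <- sprintf("r%02d", seq_len(R))
  if (is.null(colnames(frac))) colnames(frac) <- sprintf("c%02d", seq_len(C))
  if (is.null(regions)) {
    regions <- data.table(
      chrom = "chr1", start = (seq_len(R) - 1L) * 1000L,
      end = seq_len(R) * 1000L, feature_class = feature_class,
      region_id = rownames(frac)
    )
  }
  obs <- !is.na(frac)
  reads <- matrix(0L, R, C, dimnames = dimnames(frac))
  reads[obs] <- as.integer(reads_per_cell)
  ncpg <- matrix(0L, R, C, dimnames = dimnames(frac))
  ncpg[obs] <- 4L
  structure(
    list(regions = regions, cell_ids = colnames(frac),
         meth_fraction = frac, n_cpgs_covered = ncpg, total_reads = reads),
    class = "region_meth"
  )
}

two_group_table <- function(n_per_group) {
  data.table(
    cell_id = c(sprintf("c%02d", seq_len(n_per_group)),
                sprintf("c%02d", n_per_group + seq_len(n_per_group))),
    group = rep(1:2, each = n_per_group)
  )
}

# independent closed-form pooled and Welch t-tests (textbook formulas),
# used as oracles against dm_test
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

welch_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df = df))
}

# brute-force BH step-up from the definition: min over j >= rank(i) of
# p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)
    adj[i] <- min(1, min(p[ord[r:m]] * m / (r:m)))
  }
  adj
}
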
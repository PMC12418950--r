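#' Joint non-negative matrix factorization of expression and methylation
#'
#' Minimizes `||X_rna - W_rna H||^2 + lambda ||X_meth - W_meth H||^2` by
#' Lee-Seung multiplicative updates, sharing the factors-x-cells loading
#' matrix `H` between the two omics layers so the latent factors describe
#' cells jointly. Both inputs must be non-negative over the same cell set
#' (typically log1p-normalized expression and methylation fractions with
#' missing entries imputed by the region's cross-cell mean). Each cell is
#' assigned to its argmax factor. Deterministic given `seed`; the objective
#' trace is non-increasing.
#'
#' With `lambda = 0` the factorization is driven by the expression layer
#' alone and `W_meth` is fitted post hoc against the fixed `H`.
#'
#' @param X_rna genes x cells non-negative matrix
#' @param X_meth loci x cells non-negative matrix (same cells)
#' @param K number of factors (default 2)
#' @param lambda weight of the methylation layer (default 1)
#' @param seed RNG seed for the initialization
#' @param max_iter,tol stopping rule: relative objective change below `tol`
#'   or `max_iter` iterations
#' @return a `factor_model` list: `H`, `W_rna`, `W_meth`,
#'   `factor_assignment`, `objective_trace`
#' @export
joint_nmf <- function(X_rna, X_meth, K = 2, lambda = 1, seed = 1,
                      max_iter = 500, tol = 1e-6) {
  if (is.null(colnames(X_rna)) || is.null(colnames(X_meth))) {
    stop("both matrices need cell ids as column names")
  }
  if (!identical(colnames(X_rna), colnames(X_meth))) {
    miss <- union(setdiff(colnames(X_rna), colnames(X_meth)),
                  setdiff(colnames(X_meth), colnames(X_rna)))
    if (length(miss) > 0L) {
      stop("cell sets differ between layers; missing: ",
           paste(miss, collapse = ", "))
    }
    X_meth <- X_meth[, colnames(X_rna), drop = FALSE]
  }
  C <- ncol(X_rna)
  if (K > C) stop("K cannot exceed the number of cells")
  if (anyNA(X_rna) || anyNA(X_meth)) {
    stop("inputs must be complete; impute missing methylation first ",
         "(see impute_region_means)")
  }
  if (any(X_rna < 0) || any(X_meth < 0)) stop("inputs must be non-negative")
  eps <- 1e-10
  set.seed(stage_seed(seed, "joint_nmf"))
  scale0 <- sqrt(mean(X_rna) / K + eps)
  Wr <- matrix(runif(nrow(X_rna) * K, 0, scale0), ncol = K)
  Wm <- matrix(runif(nrow(X_meth) * K, 0, sqrt(mean(X_meth) / K + eps)),
               ncol = K)
  H <- matrix(runif(K * C, 0, 1), nrow = K)

  obj <- function() {
    sum((X_rna - Wr %*% H)^2) + lambda * sum((X_meth - Wm %*% H)^2)
  }
  trace <- obj()
  for (it in seq_len(max_iter)) {
    Wr <- Wr * (X_rna %*% t(H)) / (Wr %*% H %*% t(H) + eps)
    if (lambda > 0) {
      Wm <- Wm * (X_meth %*% t(H)) / (Wm %*% H %*% t(H) + eps)
      num <- t(Wr) %*% X_rna + lambda * t(Wm) %*% X_meth
      den <- (t(Wr) %*% Wr + lambda * t(Wm) %*% Wm) %*% H + eps
    } else {
      num <- t(Wr) %*% X_rna
      den <- t(Wr) %*% Wr %*% H + eps
    }
    H <- H * num / den
    trace <- c(trace, obj())
    n <- length(trace)
    if (abs(trace[n - 1] - trace[n]) < tol * max(trace[n - 1], eps)) break
  }
  if (lambda == 0) {
    # fit the methylation basis against the final H without touching it
    for (i in seq_len(50)) {
      Wm <- Wm * (X_meth %*% t(H)) / (Wm %*% H %*% t(H) + eps)
    }
  }
  dimnames(H) <- list(paste0("factor", seq_len(K)), colnames(X_rna))
  rownames(Wr) <- rownames(X_rna)
  rownames(Wm) <- rownames(X_meth)
  structure(
    list(H = H, W_rna = Wr, W_meth = Wm,
         factor_assignment = setNames(apply(H, 2L, which.max),
                                      colnames(X_rna)),
         objective_trace = trace),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat("factor_model:", nrow(x$H), "factors x", ncol(x$H), "cells\n")
  print(table(factor = x$factor_assignment))
  cat("final objective:", tail(x$objective_trace, 1), "after",
      length(x$objective_trace) - 1, "iterations\n")
  invisible(x)
}

#' Impute missing methylation entries with region cross-cell means
#'
#' NMF needs complete non-negative input; missing (uncovered) entries are
#' replaced by the region's mean over observed cells. Regions missing in
#' every cell are dropped.
#'
#' @param matrix_ a `region_meth`
#' @return a loci x cells numeric matrix without NAs
#' @export
impute_region_means <- function(matrix_) {
  m <- matrix_$meth_fraction
  keep <- rowSums(!is.na(m)) > 0
  m <- m[keep, , drop = FALSE]
  rm <- rowMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0L) m[idx] <- rm[idx[, 1L]]
  m
}

#' Rank factor markers by assigned-vs-rest contrast
#'
#' For each factor and feature, compares cells assigned to the factor against
#' all other cells with a Wilcoxon rank-sum test and a natural-log fold
#' change of means. Features with `p < alpha` and `lfc > min_fc` are
#' retained, ranked by fold change — the per-factor marker lists that
#' characterise each cluster.
#'
#' @param model a `factor_model`
#' @param data features x cells matrix (the layer to rank: expression or
#'   methylation)
#' @param alpha p-value threshold (default 0.05)
#' @param min_fc minimum natural-log fold change (default 0.25)
#' @param eps pseudo-value guarding the log (default 1e-9)
#' @return a `data.table` with `factor`, `feature_id`, `p_value`, `lfc`,
#'   `rank`
#' @export
rank_factor_markers <- function(model, data, alpha = 0.05, min_fc = 0.25,
                                eps = 1e-9) {
  stopifnot(identical(colnames(data), names(model$factor_assignment)))
  out <- list()
  for (k in sort(unique(model$factor_assignment))) {
    in_k <- model$factor_assignment == k
    if (sum(in_k) < 2L || sum(!in_k) < 2L) {
      warning("factor ", k, " has fewer than 2 assigned cells; ",
              "markers undefined")
      next
    }
    lfc <- log(rowMeans(data[, in_k, drop = FALSE]) + eps) -
      log(rowMeans(data[, !in_k, drop = FALSE]) + eps)
    p <- apply(data, 1L, function(v) {
      if (var(v) == 0) return(1)
      suppressWarnings(wilcox.test(v[in_k], v[!in_k])$p.value)
    })
    keep <- p < alpha & lfc > min_fc
    if (!any(keep)) next
    dt <- data.table(factor = k, feature_id = rownames(data)[keep],
                     p_value = p[keep], lfc = lfc[keep])
    data.table::setorder(dt, -lfc)
    dt[, rank := seq_len(.N)]
    out[[as.character(k)]] <- dt
  }
  if (length(out) == 0L) {
    return(data.table(factor = integer(), feature_id = character(),
                      p_value = numeric(), lfc = numeric(), rank = integer()))
  }
  data.table::rbindlist(out)
}

#' Per-group methylation-expression correlation with a cis-distance rule
#'
#' Candidate pairs are (locus, gene) combinations on the same chromosome with
#' the locus midpoint closer than `max_distance` (default 500 kb) to the
#' gene's TSS. Within each group, Pearson correlation is computed over cells
#' with both values present (pairwise-complete, at least `min_pairs`). A pair
#' is reported for group g when `|r_g| >= r_min` (0.5), the between-group
#' difference `|r_g - r_other| > delta_r` (0.1), and `|r_g| > r_guard` (0.2,
#' a redundant guard kept for completeness); when the other group's
#' correlation is not computable it is taken as 0 for the difference clause.
#' Zero-variance vectors skip the pair with a reason.
#'
#' @param meth_matrix a `region_meth` over the candidate loci (promoters,
#'   VMRs, CGIs)
#' @param expr_matrix genes x cells expression matrix (normalized)
#' @param gene_table internal genes table (for TSS positions)
#' @param groups table with `cell_id`, `group`
#' @param max_distance locus-midpoint-to-TSS bound in bp (default 500 000)
#' @param r_min,delta_r,r_guard the three correlation thresholds
#' @param min_pairs minimum complete observations per group (default 5)
#' @return `list(records, sign_counts, skipped)`: retained correlation
#'   records, per-group positive/negative totals, and skip reasons
#' @export
correlate_meth_expr <- function(meth_matrix, expr_matrix, gene_table, groups,
                                max_distance = 500000, r_min = 0.5,
                                delta_r = 0.1, r_guard = 0.2,
                                min_pairs = 5) {
  regions <- meth_matrix$regions
  mid <- (regions$start + regions$end) / 2
  cand <- list()
  for (gi in seq_len(nrow(gene_table))) {
    same <- which(regions$chrom == gene_table$chrom[gi])
    if (length(same) == 0L) next
    d <- abs(mid[same] - gene_table$tss[gi])
    hit <- same[d < max_distance]
    if (length(hit) > 0L) {
      cand[[length(cand) + 1L]] <- data.table(
        locus_idx = hit, gene_id = gene_table$gene_id[gi],
        distance_bp = d[d < max_distance]
      )
    }
  }
  empty <- list(
    records = data.table(locus_id = character(), gene_id = character(),
                         group = integer(), r = numeric(),
                         p_value = numeric(), distance_bp = numeric(),
                         sign = character()),
    sign_counts = data.table(group = integer(), positive = integer(),
                             negative = integer()),
    skipped = data.table(locus_id = character(), gene_id = character(),
                         reason = character())
  )
  if (length(cand) == 0L) return(empty)
  cand <- data.table::rbindlist(cand)
  cand <- cand[gene_id %in% rownames(expr_matrix)]
  if (nrow(cand) == 0L) return(empty)

  common <- intersect(meth_matrix$cell_ids, colnames(expr_matrix))
  g <- groups$group[match(common, groups$cell_id)]
  lv <- sort(unique(g[!is.na(g)]))
  stopifnot(length(lv) == 2L)
  meth <- meth_matrix$meth_fraction[, common, drop = FALSE]
  expr <- expr_matrix[, common, drop = FALSE]

  recs <- list(); skips <- list()
  for (i in seq_len(nrow(cand))) {
    li <- cand$locus_idx[i]
    gid <- cand$gene_id[i]
    mv <- meth[li, ]
    ev <- expr[gid, ]
    rr <- pp <- setNames(rep(NA_real_, 2L), lv)
    for (k in 1:2) {
      sel <- which(g == lv[k] & !is.na(mv) & !is.na(ev))
      if (length(sel) < min_pairs) next
      if (var(mv[sel]) == 0 || var(ev[sel]) == 0) {
        skips[[length(skips) + 1L]] <- data.table(
          locus_id = regions$region_id[li], gene_id = gid,
          reason = paste0("zero variance in group ", lv[k]))
        next
      }
      ct <- cor.test(mv[sel], ev[sel], method = "pearson")
      rr[k] <- unname(ct$estimate)
      pp[k] <- ct$p.value
    }
    for (k in 1:2) {
      if (is.na(rr[k])) next
      other <- if (is.na(rr[3 - k])) 0 else rr[3 - k]
      if (abs(rr[k]) >= r_min && abs(rr[k] - other) > delta_r &&
          abs(rr[k]) > r_guard) {
        recs[[length(recs) + 1L]] <- data.table(
          locus_id = regions$region_id[li], gene_id = gid,
          group = lv[k], r = rr[k], p_value = pp[k],
          distance_bp = cand$distance_bp[i],
          sign = if (rr[k] > 0) "positive" else "negative")
      }
    }
  }
  records <- if (length(recs) > 0L) data.table::rbindlist(recs) else
    empty$records
  sign_counts <- if (nrow(records) > 0L) {
    records[, .(positive = sum(sign == "positive"),
                negative = sum(sign == "negative")), by = group]
  } else empty$sign_counts
  skipped <- if (length(skips) > 0L) unique(data.table::rbindlist(skips)) else
    empty$skipped
  list(records = records, sign_counts = sign_counts, skipped = skipped)
}
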
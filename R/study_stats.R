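#' Percentage rate from counts, half-up rounded
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the convention of printed cleavage and blastocyst rates (e.g. 156 cleaved
#' of 268 oocytes prints as 58.2).
#'
#' @param numerator,denominator counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`
#' @param decimals decimal places (default 1)
#' @return the percentage
#' @export
rate_percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Mean and standard error of the mean
#'
#' SEM uses the n-1 sample standard deviation: `sd(values)/sqrt(n)`.
#'
#' @param values numeric vector, length >= 2
#' @return `c(mean, sem)`
#' @export
mean_sem <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  c(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}

#' Pooled-variance two-sample t-test for embryological endpoints
#'
#' Two-sided Student t with pooled variance. When both samples are constant
#' the statistic degenerates: equal means give `t = 0, p = 1`; unequal means
#' give an infinite statistic, reported with the sentinel `p = 1e-12`.
#'
#' @param values_a,values_b numeric vectors, each length >= 2
#' @return `list(t_stat, p_value)`
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 values per sample")
  }
  if (var(values_a) == 0 && var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(t_stat = 0, p_value = 1))
    }
    return(list(t_stat = sign(mean(values_a) - mean(values_b)) * Inf,
                p_value = 1e-12))
  }
  res <- t.test(values_a, values_b, var.equal = TRUE)
  list(t_stat = unname(res$statistic), p_value = res$p.value)
}

#' Summarise two-group embryo outcome counts
#'
#' From per-group oocyte/cleaved/blastocyst counts computes the cleavage
#' rate (cleaved / oocytes) and blastocyst rate (blastocysts / cleaved) as
#' printed percentages, with optional normality (Kolmogorov-Smirnov) and
#' variance-homogeneity diagnostics when replicate values are supplied.
#'
#' @param outcomes a data.frame with columns `group`, `n_oocytes`,
#'   `n_cleaved`, `n_blastocysts`
#' @return the table with `cleavage_rate` and `blastocyst_rate` columns added
#' @export
embryo_outcome_rates <- function(outcomes) {
  dt <- as.data.table(outcomes)
  stopifnot(all(c("group", "n_oocytes", "n_cleaved", "n_blastocysts") %in%
                  names(dt)))
  if (any(dt$n_blastocysts > dt$n_cleaved | dt$n_cleaved > dt$n_oocytes)) {
    stop("expected n_blastocysts <= n_cleaved <= n_oocytes")
  }
  dt[, cleavage_rate := rate_percent(n_cleaved, n_oocytes)]
  dt[, blastocyst_rate := rate_percent(n_blastocysts, n_cleaved)]
  dt[]
}
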
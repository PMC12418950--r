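#' @importFrom data.table data.table as.data.table setDT setnames := fread fwrite
#' @importFrom stats median rnorm rbeta rbinom rnbinom rpois runif setNames
#'   var sd cor cor.test t.test wilcox.test p.adjust pt pnorm prcomp quantile
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "n_meth", "n_unmeth", "start", "end",
  "feature_class", "region_id", "gene_id", "strand", "tss", "gene_start",
  "gene_end", "is_mito", "cell_id", "pair_id", "run_id", "variance", "rank",
  "unit", "significant", "level_label_g1", "level_label_g2", "status",
  "fdr", "direction", "p_value", "log2fc", "lfc", "cleavage_rate",
  "blastocyst_rate", "n_cleaved", "n_oocytes", "n_blastocysts", "positive",
  "negative", "V1"
))

.CLASS_VOCAB <- c("CGI", "promoter", "gene_body", "transposon",
                  "window1kb", "VMR", "imprinted_gDMR")

#' Round half-up to a fixed number of decimals
#'
#' Base `round()` rounds half to even; printed rates in study tables use
#' conventional half-up rounding, so that is what summary functions use.
#'
#' @param x numeric vector
#' @param digits decimal places (default 0)
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stable per-stage seed derived from a global seed and a stage name.
# Polynomial string hash keeps the result a valid 32-bit R integer so that
# adding or removing one stage never perturbs another stage's stream.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1999993
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h) %% 2147483587L
}

# Convert an internal 0-based half-open region table to GRanges (1-based closed)
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

# CpG point positions (internal 0-based) to GRanges width-1 ranges
cpg_to_granges <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos + 1L, width = 1L)
  )
}

# fread with transparent gzip support that does not depend on external
# decompression helpers: .gz files are inflated through a gzfile connection
fread_text <- function(path, header = FALSE, ...) {
  if (!grepl("\\.gz$", path) && file.size(path) == 0) return(data.table())
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) == 0L ||
        (header && length(lines) == 1L && !nzchar(lines))) {
      return(data.table())
    }
    fread(text = lines, header = header, sep = "\t", fill = TRUE,
          colClasses = list(character = 1), ...)
  } else {
    fread(path, header = header, sep = "\t", fill = TRUE,
          colClasses = list(character = 1), ...)
  }
}

check_feature_class <- function(feature_class) {
  if (!all(feature_class %in% .CLASS_VOCAB)) {
    bad <- setdiff(unique(feature_class), .CLASS_VOCAB)
    stop("unknown feature class: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.CLASS_VOCAB, collapse = ", "), ")")
  }
  invisible(feature_class)
}
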
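#' Read a Bismark-style coverage file of per-CpG methylation calls
#'
#' Parses the six-column coverage dialect produced by methylation extraction
#' (chrom, 1-based start, end, percent methylated, count methylated, count
#' unmethylated). The percent column is never trusted: methylation levels are
#' always recomputed from the two read counts, and a warning is raised when
#' the stored percentage disagrees with the counts by more than 0.5. Positions
#' are converted to the package-internal 0-based convention on read.
#' Zero-coverage lines are dropped. Gzip input is handled transparently.
#'
#' @param path path to a `.cov` or `.cov.gz` file
#' @return a `data.table` with columns `chrom`, `pos` (0-based), `n_meth`,
#'   `n_unmeth`, sorted by (chrom, pos)
#' @export
read_bismark_cov <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    fread_text(path),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      n_meth = integer(), n_unmeth = integer()))
  }
  if (ncol(dt) < 6L) {
    stop("coverage file ", path, " has ", ncol(dt),
         " columns; expected at least 6")
  }
  suppressWarnings({
    start1 <- as.integer(as.character(dt[[2]]))
    pct <- as.numeric(as.character(dt[[4]]))
    nm <- as.integer(as.character(dt[[5]]))
    nu <- as.integer(as.character(dt[[6]]))
  })
  bad <- which(is.na(start1) | is.na(nm) | is.na(nu) | start1 < 1L |
                 nm < 0L | nu < 0L)
  if (length(bad) > 0L) {
    stop("malformed coverage line ", bad[1], " in ", path)
  }
  cov <- nm + nu
  keep <- cov > 0L
  recomputed <- 100 * nm[keep] / cov[keep]
  stored <- pct[keep]
  off <- !is.na(stored) & abs(stored - recomputed) > 0.5
  if (any(off)) {
    warning(sum(off), " line(s) in ", path,
            " have a percent column inconsistent with the counts; ",
            "counts are used")
  }
  out <- data.table(
    chrom = as.character(dt[[1]])[keep],
    pos = start1[keep] - 1L,
    n_meth = nm[keep],
    n_unmeth = nu[keep]
  )
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Write per-CpG calls as a Bismark-style coverage file
#'
#' Inverse of [read_bismark_cov()]: internal 0-based positions are converted
#' back to 1-based and the percent column is recomputed from the counts.
#'
#' @param calls a calls `data.table` (`chrom`, `pos`, `n_meth`, `n_unmeth`)
#' @param path output path; a `.gz` suffix triggers gzip compression
#' @return `path`, invisibly
#' @export
write_bismark_cov <- function(calls, path) {
  stopifnot(all(c("chrom", "pos", "n_meth", "n_unmeth") %in% names(calls)))
  out <- data.table(
    chrom = calls$chrom,
    start = calls$pos + 1L,
    end = calls$pos + 1L,
    pct = 100 * calls$n_meth / (calls$n_meth + calls$n_unmeth),
    n_meth = calls$n_meth,
    n_unmeth = calls$n_unmeth
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Collapse plus/minus-strand calls of a CpG dyad
#'
#' A CpG site is palindromic: bisulfite reads report the cytosines at position
#' p (plus strand) and p+1 (minus strand) separately. In `merge_adjacent` mode
#' calls at adjacent positions on the same chromosome are summed into a single
#' call at the lower position, raising effective per-site coverage — useful at
#' the 0.5-3x depths typical of single-cell bisulfite libraries. Counts are
#' conserved exactly. `keep_as_is` returns the input unchanged.
#'
#' @param calls calls table sorted by (chrom, pos)
#' @param mode `"merge_adjacent"` (default) or `"keep_as_is"`
#' @return a calls `data.table`
#' @export
merge_symmetric_cpg <- function(calls, mode = c("merge_adjacent", "keep_as_is")) {
  mode <- match.arg(mode)
  if (mode == "keep_as_is") return(calls)
  n <- nrow(calls)
  if (n <= 1L) return(calls)
  if (is.unsorted(calls$pos) &&
      any(calls[, is.unsorted(pos), by = chrom]$V1)) {
    stop("calls must be sorted by (chrom, pos)")
  }
  same_chrom <- calls$chrom[-1L] == calls$chrom[-n]
  step <- calls$pos[-1L] - calls$pos[-n]
  if (any(same_chrom & step < 0L)) stop("calls must be sorted by (chrom, pos)")
  adj <- c(FALSE, same_chrom & step == 1L)
  # runs of consecutive adjacency: pair greedily from the left inside each run
  run_id <- cumsum(!adj)
  offset <- seq_len(n) - match(run_id, run_id)
  pair <- paste0(run_id, "_", offset %/% 2L)
  merged <- calls[, .(chrom = chrom[1L], pos = pos[1L],
                      n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                  by = .(pair_id = pair)]
  merged[, pair_id := NULL]
  data.table::setkey(merged, chrom, pos)
  merged[]
}

#' Read a BED file of genomic features
#'
#' BED3/BED4, 0-based half-open (kept as-is internally). When a name column
#' is present it becomes the region id; otherwise ids are synthesised as
#' `class:chrom:start-end`.
#'
#' @param path BED file (optionally gzipped)
#' @param feature_class one of `CGI`, `promoter`, `gene_body`, `transposon`,
#'   `window1kb`, `VMR`, `imprinted_gDMR`
#' @return a regions `data.table` (`chrom`, `start`, `end`, `feature_class`,
#'   `region_id`)
#' @export
read_bed <- function(path, feature_class) {
  check_feature_class(feature_class)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread_text(path)
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      feature_class = character(), region_id = character()))
  }
  if (ncol(dt) < 3L) stop("BED file ", path, " has fewer than 3 columns")
  suppressWarnings({
    s <- as.integer(as.character(dt[[2]]))
    e <- as.integer(as.character(dt[[3]]))
  })
  bad <- which(is.na(s) | is.na(e))
  if (length(bad) > 0L) stop("malformed BED line ", bad[1], " in ", path)
  empty <- which(s >= e)
  if (length(empty) > 0L) {
    stop("empty or inverted interval at BED line ", empty[1], " in ", path)
  }
  chrom <- as.character(dt[[1]])
  id <- if (ncol(dt) >= 4L && !all(is.na(dt[[4]]))) {
    as.character(dt[[4]])
  } else {
    paste0(feature_class, ":", chrom, ":", s, "-", e)
  }
  id[is.na(id) | id == ""] <-
    paste0(feature_class, ":", chrom, ":", s, "-", e)[is.na(id) | id == ""]
  data.table(chrom = chrom, start = s, end = e,
             feature_class = feature_class, region_id = id)
}

#' Write regions as BED4
#' @param regions a regions table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(regions, path) {
  fwrite(regions[, c("chrom", "start", "end", "region_id")], path,
         sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `tss` (1-based),
#' `gene_start` (1-based), `gene_end` (inclusive), `is_mito` (TRUE/FALSE or
#' 0/1). Coordinates are converted to 0-based half-open on read: `tss` becomes
#' the 0-based position of the transcription start, gene bodies become
#' `[gene_start-1, gene_end)`.
#'
#' @param path TSV file
#' @return a genes `data.table` with internal 0-based `tss`, `gene_start`,
#'   `gene_end` (half-open) and logical `is_mito`
#' @export
read_gene_table <- function(path) {
  dt <- fread_text(path, header = TRUE)
  need <- c("gene_id", "chrom", "strand", "tss", "gene_start", "gene_end",
            "is_mito")
  if (!all(need %in% names(dt))) {
    stop("gene table ", path, " missing column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  if (anyDuplicated(dt$gene_id)) stop("duplicated gene_id in ", path)
  out <- data.table(
    gene_id = as.character(dt$gene_id),
    chrom = as.character(dt$chrom),
    strand = as.character(dt$strand),
    tss = as.integer(dt$tss) - 1L,
    gene_start = as.integer(dt$gene_start) - 1L,
    gene_end = as.integer(dt$gene_end),
    is_mito = as.logical(dt$is_mito)
  )
  if (any(is.na(out$is_mito))) stop("is_mito must be defined for every gene")
  out
}

#' Write a gene annotation table (inverse of [read_gene_table()])
#' @param genes internal genes table (0-based)
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_gene_table <- function(genes, path) {
  out <- data.table(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss + 1L, gene_start = genes$gene_start + 1L,
    gene_end = genes$gene_end, is_mito = genes$is_mito
  )
  fwrite(out, path, sep = "\t", compress = "auto")
  invisible(path)
}

#' Read a genes x cells count matrix
#'
#' Accepts either a TSV (first column gene ids, header row cell ids) or a
#' MatrixMarket triplet given as `list(mtx=, rows=, cols=)` with one id per
#' line in the row/column files. Counts must be non-negative integers and ids
#' unique; a stored-zero MTX yields a dense zero matrix of the declared shape.
#'
#' @param path_or_triplet a TSV path or a `list(mtx, rows, cols)`
#' @return an integer matrix with gene rownames and cell colnames
#' @export
read_count_matrix <- function(path_or_triplet) {
  if (is.list(path_or_triplet)) {
    stopifnot(all(c("mtx", "rows", "cols") %in% names(path_or_triplet)))
    m <- as.matrix(Matrix::readMM(path_or_triplet$mtx))
    genes <- readLines(path_or_triplet$rows)
    cells <- readLines(path_or_triplet$cols)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("MTX dimensions do not match row/column id files")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    dt <- fread_text(path_or_triplet, header = TRUE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, with = FALSE])
    rownames(m) <- genes
  }
  if (anyDuplicated(rownames(m))) stop("duplicated gene ids in count matrix")
  if (anyDuplicated(colnames(m))) stop("duplicated cell ids in count matrix")
  if (any(is.na(m))) stop("missing values in count matrix")
  if (any(m < 0)) stop("negative counts in count matrix")
  if (any(m != round(m))) stop("non-integer counts in count matrix")
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV (inverse of [read_count_matrix()])
#' @param counts integer matrix with dimnames
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts))
  dt <- cbind(dt, as.data.table(counts))
  fwrite(dt, path, sep = "\t", compress = "auto")
  invisible(path)
}

#' Write any result table as TSV with a header
#' @param records a data.frame/data.table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results_table <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t", compress = "auto")
  invisible(path)
}
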
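#' Pooled SNP count tables
#'
#' A `snp_table` is the package's carrier for per-SNP, per-pool allele read
#' counts: one row per biallelic SNP with columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, and two integer columns `<pool>_ref` / `<pool>_alt` per
#' pool. Rows are sorted by chromosome then position and duplicate
#' `(chrom, pos)` records are rejected. Pools carry read counts, not
#' genotypes: the major/minor allele at a SNP is decided per pool from its
#' own counts.
#'
#' @param x A data.frame with the columns described above.
#' @param pools Character vector of pool names. If `NULL`, inferred from the
#'   `*_ref` count columns, preserving column order.
#' @return An object of class `snp_table` (a data.frame) with a `pools`
#'   attribute.
#' @examples
#' df <- data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                  ref = c("A", "C"), alt = c("G", "T"),
#'                  p1_ref = c(10L, 3L), p1_alt = c(2L, 9L))
#' snps <- as_snp_table(df)
#' pool_names(snps)
#' @export
as_snp_table <- function(x, pools = NULL) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(pools)) {
    ref_cols <- grep("_ref$", names(x), value = TRUE)
    pools <- sub("_ref$", "", ref_cols)
  }
  if (!length(pools)) stop("no pool count columns found")
  count_cols <- as.vector(rbind(paste0(pools, "_ref"), paste0(pools, "_alt")))
  missing_cols <- setdiff(count_cols, names(x))
  if (length(missing_cols)) {
    stop("missing count columns: ", paste(missing_cols, collapse = ", "))
  }

  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  bases <- c("A", "C", "G", "T")
  if (!all(x$ref %in% bases) || !all(x$alt %in% bases)) {
    stop("ref/alt alleles must be single bases in {A,C,G,T}")
  }
  if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
  for (cc in count_cols) {
    v <- x[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("counts in column '", cc, "' must be non-negative integers")
    }
    x[[cc]] <- as.integer(v)
  }

  ord <- order(x$chrom, x$pos)
  x <- x[ord, c(required, count_cols), drop = FALSE]
  if (anyDuplicated(x[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) records")
  }
  rownames(x) <- NULL
  attr(x, "pools") <- pools
  class(x) <- c("snp_table", "data.frame")
  x
}

#' @rdname as_snp_table
#' @export
pool_names <- function(x) attr(x, "pools")

#' Per-pool count and frequency matrices
#'
#' Extract per-pool read counts from a [as_snp_table()] object as an
#' n-SNP-by-n-pool matrix. `maj`/`min` are the counts of the most/least
#' observed allele per SNP per pool; `alt_freqs()` returns the alternate
#' allele read frequency, `NA` where a pool has zero depth at a SNP.
#'
#' @param snps A `snp_table`.
#' @param which One of `"ref"`, `"alt"`, `"maj"`, `"min"`.
#' @return Numeric matrix with one column per pool.
#' @export
pool_counts <- function(snps, which = c("ref", "alt", "maj", "min")) {
  which <- match.arg(which)
  pools <- pool_names(snps)
  get <- function(suffix) {
    m <- as.matrix(as.data.frame(snps)[paste0(pools, "_", suffix)])
    colnames(m) <- pools
    m
  }
  switch(which,
    ref = get("ref"),
    alt = get("alt"),
    maj = pmax(get("ref"), get("alt")),
    min = pmin(get("ref"), get("alt"))
  )
}

#' @rdname pool_counts
#' @export
alt_freqs <- function(snps) {
  ref <- pool_counts(snps, "ref")
  alt <- pool_counts(snps, "alt")
  tot <- ref + alt
  f <- alt / tot
  f[tot == 0] <- NA_real_
  f
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs, %d pools (%s)\n", nrow(x),
              length(pool_names(x)), paste(pool_names(x), collapse = ", ")))
  cat(sprintf("chromosomes: %s\n", paste(unique(x$chrom), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Genomic interval sets
#'
#' Plain carrier for BED-style intervals (0-based, half-open): columns
#' `chrom`, `start`, `end`, `name`. Used for gene models, conserved regions
#' and planted-sweep truth intervals.
#'
#' @param chrom,start,end,name Interval fields; `name` defaults to
#'   `"chrom:start-end"`.
#' @return An object of class `interval_set` (a data.frame), sorted by
#'   chromosome, start, end.
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start != floor(start)) ||
      any(end != floor(end))) {
    stop("interval bounds must be integers")
  }
  if (any(start >= end)) stop("intervals must satisfy start < end")
  if (is.null(name)) name <- sprintf("%s:%d-%d", chrom, start, end)
  x <- data.frame(chrom = chrom, start = start, end = end,
                  name = as.character(name), stringsAsFactors = FALSE)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  x
}

# interval_set -> GRanges (internal); intervals are 0-based half-open,
# GRanges 1-based closed.
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}
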
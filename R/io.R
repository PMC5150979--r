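#' Read pooled allele depths from a multi-sample VCF
#'
#' Each VCF sample is one population pool whose `AD` FORMAT field carries the
#' per-allele read depths (GATK-style `ref,alt`). Genotype calls are ignored:
#' pools have no individual genotypes, only read counts. Only biallelic SNP
#' records are kept; indels, multiallelic records and records lacking usable
#' `AD` values for every requested pool are dropped and tallied in the
#' `drop_summary` attribute of the result.
#'
#' @param path Path to a VCF (4.x) file.
#' @param pool_names Sample names to load as pools. `NULL` loads all samples.
#' @return A [as_snp_table()] object with a `drop_summary` attribute
#'   (named integer vector with elements `indel`, `multiallelic`, `no_ad`).
#' @export
read_pool_vcf <- function(path, pool_names = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (is.null(pool_names)) pool_names <- samples
  absent <- setdiff(pool_names, samples)
  if (length(absent)) {
    stop("sample(s) not in VCF: ", paste(absent, collapse = ", "),
         "; available: ", paste(samples, collapse = ", "))
  }

  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & ref %in% bases & alt %in% bases
  indel <- !multi & !snp
  drops <- c(indel = sum(indel), multiallelic = sum(multi), no_ad = 0L)

  ad <- vcfR::extract.gt(vcf, element = "AD")
  keep <- which(snp)
  n <- length(keep)
  counts <- matrix(NA_integer_, n, 2L * length(pool_names))
  ok <- rep(TRUE, n)
  for (k in seq_along(pool_names)) {
    parts <- strsplit(ad[keep, pool_names[k]], ",", fixed = TRUE)
    two <- lengths(parts) >= 2L
    rc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    ac <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    bad <- !two | is.na(rc) | is.na(ac) | rc < 0L | ac < 0L
    ok <- ok & !bad
    counts[, 2L * k - 1L] <- rc
    counts[, 2L * k] <- ac
  }
  drops["no_ad"] <- sum(!ok)
  keep <- keep[ok]
  counts <- counts[ok, , drop = FALSE]

  df <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                   ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE)
  cn <- as.vector(rbind(paste0(pool_names, "_ref"), paste0(pool_names, "_alt")))
  df[cn] <- as.data.frame(counts)
  out <- as_snp_table(df, pools = pool_names)
  attr(out, "drop_summary") <- drops
  out
}

#' Read and write the pooled allele-count TSV
#'
#' The count table is a tab-separated dialect with header
#' `chrom pos ref alt <pool>_ref <pool>_alt ...`, positions 1-based. It
#' round-trips exactly through [write_count_table()] / [read_count_table()].
#' Unsorted input is sorted on load with a notice; non-integer or negative
#' counts are an error naming the offending line.
#'
#' @param path File path.
#' @param snps A [as_snp_table()] object (for writing).
#' @return `read_count_table()` returns a `snp_table`;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(x))) {
    stop("count table must start with columns: ", paste(required, collapse = ", "))
  }
  count_cols <- setdiff(names(x), required)
  x$pos <- as.integer(x$pos)
  for (cc in count_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      stop(sprintf("non-integer count '%s' in column %s at line %d",
                   x[[cc]][bad[1L]], cc, bad[1L] + 1L))
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop(sprintf("negative count at line %d (column %s)", neg[1L] + 1L, cc))
    }
    x[[cc]] <- as.integer(v)
  }
  ord <- order(x$chrom, x$pos)
  if (!identical(ord, seq_len(nrow(x)))) {
    message("count table not sorted by (chrom, pos); sorting on load")
  }
  as_snp_table(x)
}

#' @rdname read_count_table
#' @export
write_count_table <- function(path, snps) {
  stopifnot(inherits(snps, "snp_table"))
  utils::write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED file of named intervals
#'
#' Accepts BED3+ (0-based, half-open). The fourth column, when present, is
#' used as the interval name; otherwise names default to
#' `"chrom:start-end"`. Input need not be sorted; the result is.
#'
#' @param path Path to a BED file.
#' @return An [interval_set()].
#' @export
read_intervals_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("BED file must have at least 3 columns")
  start <- suppressWarnings(as.numeric(x[[2L]]))
  end <- suppressWarnings(as.numeric(x[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval (start >= end) at line %d", bad[1L]))
  }
  name <- if (ncol(x) >= 4L) as.character(x[[4L]]) else NULL
  if (!is.null(name)) {
    blank <- is.na(name) | name == ""
    name[blank] <- sprintf("%s:%d-%d", x[[1L]][blank], start[blank], end[blank])
  }
  interval_set(x[[1L]], start, end, name)
}

#' @rdname read_intervals_bed
#' @param intervals An [interval_set()].
#' @export
write_intervals_bed <- function(path, intervals) {
  utils::write.table(as.data.frame(intervals)[c("chrom", "start", "end", "name")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Write per-window scores as a BED-like TSV
#'
#' One row per (window, pool): `chrom start end pop n_snps sum_nmaj sum_nmin
#' hp zhp di`, coordinates 0-based half-open, floats with six decimals,
#' missing scores as `NA`. Rows are ordered by (chrom, start, pop), so
#' re-running on the same input produces a byte-identical file.
#'
#' @param path Output path.
#' @param scores A [score_windows()] result.
#' @return `path`, invisibly.
#' @export
write_window_scores <- function(path, scores) {
  stopifnot(inherits(scores, "window_scores"))
  w <- scores$windows
  pools <- scores$pools
  rows <- do.call(rbind, lapply(pools, function(p) {
    di <- if (p %in% colnames(scores$di)) scores$di[, p] else rep(NA_real_, nrow(w))
    data.frame(chrom = w$chrom, start = w$start, end = w$end, pop = p,
               n_snps = scores$n_snps,
               sum_nmaj = scores$sum_nmaj[, p], sum_nmin = scores$sum_nmin[, p],
               hp = fmt_num(scores$hp[, p]), zhp = fmt_num(scores$zhp[, p]),
               di = fmt_num(di), stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$chrom, rows$start, rows$pop), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write candidate loci
#'
#' `write_loci_bed()` emits a BED6-like file: `chrom start end name score
#' strand` with `name` the comma-joined overlapping genes (`.` if none),
#' `score` the locus max di (0 when undefined) and strand `.`.
#' `write_locus_table()` emits the full locus TSV (criterion, min_zhp,
#' max_di, n_windows, genes).
#'
#' @param path Output path.
#' @param loci A locus data.frame from [candidate_loci()] components.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(path, loci) {
  genes <- if ("genes" %in% names(loci)) loci$genes else rep("", nrow(loci))
  bed <- data.frame(chrom = loci$chrom, start = loci$start, end = loci$end,
                    name = ifelse(is.na(genes) | genes == "", ".", genes),
                    score = fmt_num(ifelse(is.na(loci$max_di), 0, loci$max_di)),
                    strand = ".", stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_bed
#' @export
write_locus_table <- function(path, loci) {
  out <- as.data.frame(loci)
  for (cc in intersect(c("min_zhp", "max_di"), names(out))) {
    out[[cc]] <- fmt_num(out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two tab-separated columns, `chrom` and `length` (bp); a header line is
#' detected and skipped if the second field is non-numeric.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_lengths <- function(path) {
  x <- utils::read.delim(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(x) && is.na(suppressWarnings(as.numeric(x[1L, 2L])))) {
    x <- x[-1L, , drop = FALSE]
  }
  lens <- as.numeric(x[[2L]])
  if (any(is.na(lens)) || any(lens <= 0)) stop("invalid chromosome lengths")
  stats::setNames(lens, as.character(x[[1L]]))
}
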
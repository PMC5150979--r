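#' Flag windows under the dual selection criterion
#'
#' A window is flagged low-ZHp when `ZHp <= zhp_threshold` (inclusive
#' boundary) and high-di when its di value reaches the `di_quantile`
#' quantile of all defined di values for the focal pool (linear
#' interpolation between order statistics; ties at the cutoff are
#' included). Only windows with defined scores can be flagged. The
#' realised di cutoff is returned so alternative quantile conventions can
#' be audited.
#'
#' @param scores A [score_windows()] result.
#' @param focal Focal pool name.
#' @param zhp_threshold ZHp threshold (default -4).
#' @param di_quantile Quantile of di defining "extremely high" (default
#'   0.99, the top 1 percent).
#' @return A `window_flags` list: logical vectors `low_zhp`, `high_di`
#'   (one element per window), the realised `di_cutoff`, and the
#'   parameters used.
#' @export
select_windows <- function(scores, focal, zhp_threshold = -4,
                           di_quantile = 0.99) {
  stopifnot(inherits(scores, "window_scores"))
  if (!focal %in% colnames(scores$di)) {
    stop("no di scores for focal pool: ", focal)
  }
  zhp <- scores$zhp[, focal]
  di <- scores$di[, focal]
  if (all(is.na(zhp)) && all(is.na(di))) {
    stop("no windows with defined scores for pool ", focal)
  }
  low_zhp <- !is.na(zhp) & zhp <= zhp_threshold
  dv <- di[!is.na(di)]
  if (!length(dv)) stop("no windows with defined di for pool ", focal)
  di_cutoff <- as.numeric(stats::quantile(dv, di_quantile, type = 7, names = FALSE))
  high_di <- !is.na(di) & di >= di_cutoff
  structure(list(focal = focal, low_zhp = low_zhp, high_di = high_di,
                 di_cutoff = di_cutoff, zhp_threshold = zhp_threshold,
                 di_quantile = di_quantile),
            class = "window_flags")
}

#' Merge flagged windows into candidate loci
#'
#' Overlapping or book-ended flagged windows on the same chromosome merge
#' into one locus; per locus the most negative member ZHp (`min_zhp`), the
#' largest member di (`max_di`) and the member count (`n_windows`) are
#' aggregated. Result loci are pairwise disjoint and sorted.
#'
#' @param chrom,start,end Flagged window coordinates (0-based half-open).
#' @param zhp,di Optional per-window scores to aggregate.
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `min_zhp`,
#'   `max_di`.
#' @export
merge_windows <- function(chrom, start, end, zhp = NULL, di = NULL) {
  if (!length(chrom)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      min_zhp = numeric(0), max_di = numeric(0),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  agg <- function(v, f) {
    if (is.null(v)) return(rep(NA_real_, length(red)))
    vapply(revmap, function(ix) {
      vv <- v[ix][!is.na(v[ix])]
      if (length(vv)) f(vv) else NA_real_
    }, numeric(1))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1,
             end = GenomicRanges::end(red),
             n_windows = lengths(revmap),
             min_zhp = agg(zhp, min), max_di = agg(di, max),
             stringsAsFactors = FALSE)
}

#' Intersect low-ZHp and high-di loci
#'
#' Returns the base-pair intersections (>= 1 bp) of loci called by the two
#' criteria; each intersection carries `min_zhp` from the ZHp-side locus
#' and `max_di` from the di-side locus.
#'
#' @param zhp_loci,di_loci Locus data.frames from [merge_windows()].
#' @return data.frame of intersection loci with `criterion = "both"`.
#' @export
intersect_loci <- function(zhp_loci, di_loci) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), criterion = character(0),
                      min_zhp = numeric(0), max_di = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (!nrow(zhp_loci) || !nrow(di_loci)) return(empty)
  a <- GenomicRanges::GRanges(zhp_loci$chrom,
                              IRanges::IRanges(zhp_loci$start + 1, zhp_loci$end))
  b <- GenomicRanges::GRanges(di_loci$chrom,
                              IRanges::IRanges(di_loci$start + 1, di_loci$end))
  # disjoint chromosome sets are a legitimate (empty) intersection
  hits <- suppressWarnings(GenomicRanges::findOverlaps(a, b, minoverlap = 1L))
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  pint <- GenomicRanges::pintersect(a[q], b[s])
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(pint)),
                    start = GenomicRanges::start(pint) - 1,
                    end = GenomicRanges::end(pint),
                    criterion = "both",
                    min_zhp = zhp_loci$min_zhp[q],
                    max_di = di_loci$max_di[s],
                    n_windows = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate loci with overlapping genes
#'
#' A gene is attached to a locus when their intervals overlap by at least
#' 1 bp under the half-open convention (a gene abutting the locus end is
#' not attached). Gene names are comma-joined in genomic order.
#'
#' @param loci Locus data.frame (`chrom`, `start`, `end`, ...).
#' @param genes An [interval_set()] of gene intervals.
#' @return `loci` with a `genes` character column added.
#' @export
annotate_loci <- function(loci, genes) {
  loci$genes <- rep("", nrow(loci))
  if (!nrow(loci) || is.null(genes) || !nrow(genes)) return(loci)
  a <- GenomicRanges::GRanges(loci$chrom,
                              IRanges::IRanges(loci$start + 1, loci$end))
  b <- as_granges(genes)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(a, b, minoverlap = 1L))
  if (length(hits)) {
    by_locus <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (qi in names(by_locus)) {
      ix <- by_locus[[qi]]
      ix <- ix[order(genes$start[ix], genes$end[ix])]
      loci$genes[as.integer(qi)] <- paste(genes$name[ix], collapse = ",")
    }
  }
  loci
}

#' Candidate selective loci for one focal pool
#'
#' Convenience wrapper running [select_windows()], [merge_windows()] per
#' criterion, [intersect_loci()] for the dual criterion and (optionally)
#' [annotate_loci()]. Putative selective loci are the `both` set: regions
#' simultaneously showing extremely low pooled heterozygosity and
#' extremely high lineage differentiation.
#'
#' @inheritParams select_windows
#' @param genes Optional [interval_set()] of gene intervals.
#' @return List with locus data.frames `low_zhp`, `high_di`, `both`, the
#'   realised `di_cutoff` and the `flags`.
#' @export
candidate_loci <- function(scores, focal, zhp_threshold = -4,
                           di_quantile = 0.99, genes = NULL) {
  flags <- select_windows(scores, focal, zhp_threshold, di_quantile)
  w <- scores$windows
  zhp <- scores$zhp[, focal]
  di <- scores$di[, focal]
  mk <- function(sel, criterion) {
    loci <- merge_windows(w$chrom[sel], w$start[sel], w$end[sel],
                          zhp = zhp[sel], di = di[sel])
    if (nrow(loci)) loci$criterion <- criterion
    else loci$criterion <- character(0)
    loci[c("chrom", "start", "end", "criterion", "min_zhp", "max_di", "n_windows")]
  }
  low <- mk(flags$low_zhp, "low_zhp")
  high <- mk(flags$high_di, "high_di")
  both <- intersect_loci(low, high)
  if (!is.null(genes)) {
    low <- annotate_loci(low, genes)
    high <- annotate_loci(high, genes)
    both <- annotate_loci(both, genes)
  }
  list(low_zhp = low, high_di = high, both = both,
       di_cutoff = flags$di_cutoff, flags = flags)
}

#' Breed-specific SNPs within (flanked) genes
#'
#' A SNP is breed-specific for the focal pool when (a) the focal pool's
#' major allele is the alternate (non-reference) allele, i.e. its alternate
#' read frequency exceeds `min_alt_freq`; (b) every other pool with reads
#' at the site has the reference allele as its major allele; (c) the
#' position lies within a gene interval extended by `flank` bp on both
#' sides; and (d), when a conserved-region interval set is supplied, the
#' position also falls in a conserved interval. Pools with zero depth at a
#' site are uninformative and do not veto. The major-allele test is used
#' rather than fixation because pools are rarely fully fixed.
#'
#' @param snps A [as_snp_table()] object (>= 2 pools).
#' @param focal Focal pool name.
#' @param genes [interval_set()] of gene intervals.
#' @param flank Flank size in bp added to both gene ends (default 1000).
#' @param conserved Optional [interval_set()] of conserved regions.
#' @param min_alt_freq Minimum focal alternate read frequency, exclusive
#'   (default 0.5: the alternate allele must be the major allele).
#' @return data.frame of qualifying SNPs: `chrom`, `pos`, `ref`, `alt`,
#'   `focal_alt_freq`, `genes`.
#' @export
breed_specific_snps <- function(snps, focal, genes, flank = 1000,
                                conserved = NULL, min_alt_freq = 0.5) {
  pools <- pool_names(snps)
  if (!focal %in% pools) stop("focal pool absent: ", focal)
  if (length(pools) < 2L) stop("need at least 2 pools")
  freq <- alt_freqs(snps)
  f_focal <- freq[, focal]
  others <- setdiff(pools, focal)
  focal_ok <- !is.na(f_focal) & f_focal > min_alt_freq
  others_ok <- rep(TRUE, nrow(snps))
  for (p in others) {
    fp <- freq[, p]
    others_ok <- others_ok & (is.na(fp) | fp < 0.5)
  }
  cand <- which(focal_ok & others_ok)
  if (!length(cand)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      focal_alt_freq = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  pts <- GenomicRanges::GRanges(snps$chrom[cand],
                                IRanges::IRanges(snps$pos[cand], width = 1L))
  flanked <- interval_set(genes$chrom, pmax(0, genes$start - flank),
                          genes$end + flank, genes$name)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pts, as_granges(flanked)))
  in_gene <- unique(S4Vectors::queryHits(hits))
  gene_names <- vapply(seq_along(cand), function(i) {
    ix <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    paste(unique(flanked$name[ix]), collapse = ",")
  }, character(1))
  keep <- seq_along(cand) %in% in_gene
  if (!is.null(conserved) && nrow(conserved)) {
    chits <- suppressWarnings(GenomicRanges::findOverlaps(pts, as_granges(conserved)))
    keep <- keep & seq_along(cand) %in% unique(S4Vectors::queryHits(chits))
  }
  cand <- cand[keep]
  data.frame(chrom = snps$chrom[cand], pos = snps$pos[cand],
             ref = snps$ref[cand], alt = snps$alt[cand],
             focal_alt_freq = f_focal[cand], genes = gene_names[keep],
             stringsAsFactors = FALSE)
}
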
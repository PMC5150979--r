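#' Count-level SNP filtering
#'
#' Mirrors pool-seq variant-calling hygiene at the count level: (1) pools
#' whose total depth at a SNP is below `min_depth` contribute nothing (their
#' counts are zeroed); (2) a SNP is kept only if at least one pool still
#' shows `min_alt_reads` or more alternate reads (the count-level
#' approximation of requiring several independent reads supporting the
#' non-reference allele; read start sites are not available from counts);
#' (3) optionally, SNPs whose pooled minor-allele frequency across all
#' pools is below `maf_floor` are dropped. The filter is idempotent:
#' applying it twice equals applying it once.
#'
#' @param snps A [as_snp_table()] object.
#' @param min_alt_reads Minimum alternate reads in at least one pool
#'   (default 3).
#' @param min_depth Minimum per-pool total depth for counts to be retained
#'   (default 4).
#' @param maf_floor Minimum across-pools pooled minor allele frequency
#'   (default 0, disabled).
#' @return A filtered `snp_table`.
#' @export
filter_snps <- function(snps, min_alt_reads = 3, min_depth = 4,
                        maf_floor = 0) {
  stopifnot(inherits(snps, "snp_table"))
  pools <- pool_names(snps)
  df <- as.data.frame(snps)
  ref <- pool_counts(snps, "ref")
  alt <- pool_counts(snps, "alt")
  tot <- ref + alt
  low <- tot > 0 & tot < min_depth
  ref[low] <- 0L
  alt[low] <- 0L
  for (p in pools) {
    df[[paste0(p, "_ref")]] <- ref[, p]
    df[[paste0(p, "_alt")]] <- alt[, p]
  }
  max_alt <- do.call(pmax, as.data.frame(alt))
  keep <- max_alt >= min_alt_reads
  if (maf_floor > 0) {
    ta <- rowSums(alt)
    tr <- rowSums(ref)
    t2 <- ta + tr
    pmaf <- ifelse(t2 > 0, pmin(ta, tr) / t2, 0)
    keep <- keep & pmaf >= maf_floor
  }
  as_snp_table(df[keep, , drop = FALSE], pools = pools)
}

#' Minor-allele-frequency spectrum of one pool
#'
#' Per SNP with nonzero depth in the pool, the minor allele frequency is
#' `min_count / (maj_count + min_count)`, binned into the ten classes
#' [0, 0.05), [0.05, 0.10), ..., [0.45, 0.50] — left-closed bins with the
#' top bin closed at 0.5 so perfectly balanced SNPs are counted.
#'
#' @param snps A [as_snp_table()] object.
#' @param pool Pool name.
#' @return A `maf_spectrum` data.frame: `bin_low`, `bin_high`, `count`,
#'   `fraction`, with attributes `pool` and `total` (nonzero-depth SNPs).
#' @export
maf_spectrum <- function(snps, pool) {
  if (!pool %in% pool_names(snps)) stop("unknown pool: ", pool)
  maj <- pool_counts(snps, "maj")[, pool]
  mn <- pool_counts(snps, "min")[, pool]
  tot <- maj + mn
  use <- tot > 0
  maf <- mn[use] / tot[use]
  bin <- pmin(floor(maf / 0.05), 9) + 1L
  counts <- tabulate(bin, nbins = 10L)
  total <- sum(use)
  out <- data.frame(bin_low = 0.05 * (0:9), bin_high = 0.05 * (1:10),
                    count = counts,
                    fraction = if (total > 0) counts / total else rep(0, 10L))
  attr(out, "pool") <- pool
  attr(out, "total") <- total
  class(out) <- c("maf_spectrum", "data.frame")
  out
}

#' Heterozygous / homozygous SNP composition of one pool
#'
#' Among SNPs with nonzero depth in the pool: homozygous means the
#' alternate allele is fixed (alternate read frequency 1, a fixed
#' non-reference difference); heterozygous means both alleles are observed
#' (frequency strictly between 0 and 1). Sites where only the reference
#' allele is read are not variants in this pool and are counted in
#' neither class.
#'
#' @param snps A [as_snp_table()] object.
#' @param pool Pool name.
#' @return Named integer vector `c(homozygous, heterozygous)`.
#' @export
het_hom_counts <- function(snps, pool) {
  if (!pool %in% pool_names(snps)) stop("unknown pool: ", pool)
  ref <- pool_counts(snps, "ref")[, pool]
  alt <- pool_counts(snps, "alt")[, pool]
  tot <- ref + alt
  f <- alt[tot > 0] / tot[tot > 0]
  c(homozygous = sum(f == 1), heterozygous = sum(f > 0 & f < 1))
}
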
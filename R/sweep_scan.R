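#' Genome-wide selective-sweep scan from pooled allele counts
#'
#' Runs the full scan: builds the sliding-window skeleton over the
#' autosomes, assigns SNPs, scores windows (pooled heterozygosity Hp, its
#' Z-transform ZHp, pairwise window FST and the di statistic), and calls
#' candidate selective loci for each focal pool under the dual criterion —
#' extremely low ZHp (`ZHp <= zhp_threshold`) and extremely high di (top
#' `1 - di_quantile` fraction). Regions passing both criteria
#' simultaneously (`both`) are the putative selective loci.
#'
#' @param snps A [as_snp_table()] of pooled allele read counts.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param autosomes Chromosomes to scan (default: all in `chrom_lengths`);
#'   sex chromosomes should be excluded.
#' @param pools Pools to score (default: all).
#' @param focal Pools for which di and candidate loci are computed
#'   (default: all scored pools).
#' @param window_size,step Sliding-window width and step in bp (defaults
#'   150 kb and 75 kb).
#' @param min_snps Minimum SNPs for a window to be scored (default 10).
#' @param zhp_threshold ZHp selection threshold (default -4, inclusive).
#' @param di_quantile di selection quantile (default 0.99).
#' @param genes Optional [interval_set()] of genes for locus annotation.
#' @return An object of class `sweep_scan`: list with `scores` (a
#'   [score_windows()] object), `loci` (per focal pool, the
#'   [candidate_loci()] result), the parameters, and the matched call.
#' @examples
#' cfg <- sim_config(c(chr1 = 3e6), n_pools = 3, seed = 7,
#'                   sweeps = data.frame(chrom = "chr1", start = 1e6,
#'                                       end = 1.3e6, pool = "pool01", s = 0.95))
#' sim <- simulate_genome(cfg)
#' scan <- sweep_scan(sim$snps, cfg$chrom_lengths, focal = "pool01")
#' summary(scan)
#' @export
sweep_scan <- function(snps, chrom_lengths, autosomes = names(chrom_lengths),
                       pools = pool_names(snps), focal = pools,
                       window_size = 150000, step = 75000, min_snps = 10,
                       zhp_threshold = -4, di_quantile = 0.99, genes = NULL) {
  frame <- make_windows(chrom_lengths, autosomes, window_size, step)
  frame <- assign_snps(snps, frame)
  scores <- score_windows(snps, frame, pools = pools, focal = focal,
                          min_snps = min_snps)
  loci <- lapply(stats::setNames(focal, focal), function(f) {
    candidate_loci(scores, f, zhp_threshold = zhp_threshold,
                   di_quantile = di_quantile, genes = genes)
  })
  structure(list(scores = scores, loci = loci, focal = focal,
                 params = list(window_size = window_size, step = step,
                               min_snps = min_snps,
                               zhp_threshold = zhp_threshold,
                               di_quantile = di_quantile),
                 n_skipped_snps = frame$n_skipped, call = match.call()),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  s <- x$scores
  cat("Selective-sweep scan of pooled sequencing data\n")
  cat(sprintf("  %d windows (%g kb, step %g kb), %d included (>= %g SNPs)\n",
              nrow(s$windows), x$params$window_size / 1000,
              x$params$step / 1000, sum(s$included), x$params$min_snps))
  cat(sprintf("  pools: %s\n", paste(s$pools, collapse = ", ")))
  for (f in x$focal) {
    cat(sprintf("  %s: %d low-ZHp loci, %d high-di loci, %d dual-criterion loci (di cutoff %.3f)\n",
                f, nrow(x$loci[[f]]$low_zhp), nrow(x$loci[[f]]$high_di),
                nrow(x$loci[[f]]$both), x$loci[[f]]$di_cutoff))
  }
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  s <- object$scores
  per_focal <- do.call(rbind, lapply(object$focal, function(f) {
    l <- object$loci[[f]]
    data.frame(pool = f,
               n_low_zhp_windows = sum(l$flags$low_zhp),
               n_high_di_windows = sum(l$flags$high_di),
               di_cutoff = l$di_cutoff,
               n_low_zhp_loci = nrow(l$low_zhp),
               n_high_di_loci = nrow(l$high_di),
               n_both_loci = nrow(l$both),
               min_zhp = suppressWarnings(min(s$zhp[, f], na.rm = TRUE)),
               max_di = suppressWarnings(max(s$di[, f], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  structure(list(n_windows = nrow(s$windows), n_included = sum(s$included),
                 params = object$params, pools = s$pools,
                 per_focal = per_focal, loci = object$loci),
            class = "summary.sweep_scan")
}

#' @export
print.summary.sweep_scan <- function(x, ...) {
  cat(sprintf("Windows: %d total, %d scored; pools: %s\n", x$n_windows,
              x$n_included, paste(x$pools, collapse = ", ")))
  cat(sprintf("Selection: ZHp <= %g and di >= top %g%% cutoff\n",
              x$params$zhp_threshold, 100 * (1 - x$params$di_quantile)))
  print(x$per_focal, row.names = FALSE)
  for (f in x$per_focal$pool) {
    b <- x$loci[[f]]$both
    if (nrow(b)) {
      cat(sprintf("\nDual-criterion loci for %s:\n", f))
      print(b, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Plot a sweep scan along the genome
#'
#' Manhattan-style plot of per-window ZHp (or di) for one focal pool,
#' windows at their genomic midpoints concatenated across chromosomes,
#' with the selection threshold (ZHp) or the realised top-quantile cutoff
#' (di) drawn as a dashed line and flagged windows highlighted.
#'
#' @param x A [sweep_scan()] object.
#' @param focal Focal pool (default: first).
#' @param statistic `"zhp"` or `"di"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sweep_scan <- function(x, focal = x$focal[1L],
                            statistic = c("zhp", "di"), ...) {
  statistic <- match.arg(statistic)
  s <- x$scores
  w <- s$windows
  chroms <- unique(w$chrom)
  offsets <- stats::setNames(cumsum(c(0, utils::head(
    vapply(chroms, function(ch) max(w$end[w$chrom == ch]), numeric(1)), -1L))),
    chroms)
  xc <- offsets[w$chrom] + (w$start + w$end) / 2
  y <- if (statistic == "zhp") s$zhp[, focal] else s$di[, focal]
  col <- ifelse(match(w$chrom, chroms) %% 2L == 0L, "grey55", "grey30")
  l <- x$loci[[focal]]
  flagged <- if (statistic == "zhp") l$flags$low_zhp else l$flags$high_di
  col[flagged] <- "firebrick"
  graphics::plot(xc, y, pch = 20, cex = 0.5, col = col,
                 xlab = "genomic position (concatenated chromosomes)",
                 ylab = if (statistic == "zhp") "ZHp" else "di",
                 main = sprintf("%s (%s)", focal, statistic), ...)
  thr <- if (statistic == "zhp") x$params$zhp_threshold else l$di_cutoff
  graphics::abline(h = thr, lty = 2, col = "firebrick")
  invisible(x)
}
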
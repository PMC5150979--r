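# population (n-denominator) standard deviation; the package-wide convention
# for ZHp and di standardisation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-window major/minor allele read sums for one pool
#'
#' For each window, sums the reads of the most observed (`sum_nmaj`) and
#' least observed (`sum_nmin`) allele over member SNPs, with major/minor
#' polarity decided per SNP from this pool's own counts. SNPs with zero
#' depth in the pool contribute (0, 0); empty windows yield (0, 0).
#'
#' @param snps A [as_snp_table()] object.
#' @param frame An [assign_snps()]-filled window frame.
#' @param pool Pool name.
#' @return data.frame with per-window `sum_nmaj`, `sum_nmin`.
#' @export
window_allele_sums <- function(snps, frame, pool) {
  if (is.null(frame$membership)) stop("frame has no SNP assignment; run assign_snps()")
  if (!pool %in% pool_names(snps)) stop("unknown pool: ", pool)
  ref <- snps[[paste0(pool, "_ref")]]
  alt <- snps[[paste0(pool, "_alt")]]
  maj <- pmax(ref, alt)
  mn <- pmin(ref, alt)
  W <- nrow(frame$windows)
  m <- frame$membership
  sum_at <- function(v) {
    out <- numeric(W)
    if (nrow(m)) {
      s <- rowsum(v[m$snp], m$window)
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
  data.frame(sum_nmaj = sum_at(maj), sum_nmin = sum_at(mn))
}

#' Pooled heterozygosity of a window
#'
#' `Hp = 2 * sum_nmaj * sum_nmin / (sum_nmaj + sum_nmin)^2`, computed from
#' the summed major/minor allele read counts of a window. Hp lies in
#' [0, 0.5], is 0.5 when major and minor reads balance, 0 when no minor
#' reads are observed, and is undefined (`NA`) when a window has no reads.
#' The statistic is scale-invariant: multiplying both sums by a constant
#' leaves it unchanged.
#'
#' @param sum_nmaj,sum_nmin Non-negative numeric vectors of summed reads.
#' @return Numeric vector of Hp values.
#' @examples
#' pooled_heterozygosity(30, 10)  # 0.375
#' @export
pooled_heterozygosity <- function(sum_nmaj, sum_nmin) {
  if (any(sum_nmaj < 0, na.rm = TRUE) || any(sum_nmin < 0, na.rm = TRUE)) {
    stop("allele read sums must be non-negative")
  }
  tot <- sum_nmaj + sum_nmin
  hp <- 2 * sum_nmaj * sum_nmin / tot^2
  hp[!is.na(tot) & tot == 0] <- NA_real_
  hp
}

#' Z-transform window heterozygosities
#'
#' `ZHp = (Hp - mean(Hp)) / sd(Hp)` with the mean and population
#' (n-denominator) standard deviation taken over windows with defined Hp;
#' windows with missing Hp stay missing and do not enter the moments. The
#' realised mean and sd are attached as attributes `mu` and `sigma`.
#'
#' @param values Numeric vector of per-window Hp for one pool (may contain
#'   `NA` for excluded windows).
#' @return Numeric vector of ZHp values with attributes `mu`, `sigma`.
#' @export
z_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 windows with defined values")
  mu <- mean(values[ok])
  sigma <- pop_sd(values[ok])
  if (sigma == 0) stop("degenerate heterozygosity distribution (sd = 0)")
  structure((values - mu) / sigma, mu = mu, sigma = sigma)
}

#' Per-SNP FST components
#'
#' Nei/Hudson-style components from two pool allele frequencies: with
#' `pbar = (p1 + p2) / 2`, total heterozygosity `HT = 2 pbar (1 - pbar)`
#' and mean within-pool heterozygosity `HS = p1 (1 - p1) + p2 (1 - p2)`,
#' returns the pair `(HT - HS, HT)`. SNPs with `HT = 0` (both pools fixed
#' for the same allele) are uninformative and are excluded from window
#' sums by [window_fst()].
#'
#' @param p1,p2 Allele frequencies in the two pools, each in [0, 1]
#'   (`alt / (ref + alt)` from read counts). Vectorised.
#' @return List with numeric vectors `num` (HT - HS) and `den` (HT).
#' @examples
#' c_ <- snp_fst(0.8, 0.2); c_$num / c_$den  # 0.36
#' @export
snp_fst <- function(p1, p2) {
  rng <- range(c(p1, p2), na.rm = TRUE)
  if (length(p1) && (rng[1L] < 0 || rng[2L] > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- p1 * (1 - p1) + p2 * (1 - p2)
  list(num = ht - hs, den = ht)
}

#' Window FST as a ratio of averages
#'
#' Sums the per-SNP numerators and denominators of [snp_fst()] over the
#' informative member SNPs of a window (those with `den > 0` and defined
#' frequencies in both pools) and returns `sum(num) / sum(den)` — the
#' ratio-of-averages estimator. `NA` when no SNP is informative. Small
#' negative values are possible and deliberately retained: clamping at zero
#' would bias the genome-wide mean used by the di statistic.
#'
#' @param num,den Per-SNP components from [snp_fst()] for one window.
#' @return Scalar window FST (or `NA`).
#' @export
window_fst <- function(num, den) {
  inf <- !is.na(den) & !is.na(num) & den > 0
  if (!any(inf)) return(NA_real_)
  sum(num[inf]) / sum(den[inf])
}

#' The di lineage-differentiation statistic
#'
#' For focal pool i and window w,
#' `di(w) = sum over j != i of (FST_ij(w) - mean(FST_ij)) / sd(FST_ij)`,
#' where the mean and population sd are taken per pair across all windows
#' with defined FST. di is defined only for windows where every pair
#' involving the focal pool has a defined FST. Large di marks windows where
#' the focal lineage is unusually differentiated from all other pools at
#' once.
#'
#' @param fst Numeric matrix of window FST values, one column per pool
#'   pair (may contain `NA`).
#' @param pair_i,pair_j Character vectors naming the two pools of each
#'   column of `fst`.
#' @param focal Focal pool name.
#' @return Numeric vector of per-window di values.
#' @export
di_statistic <- function(fst, pair_i, pair_j, focal) {
  fst <- as.matrix(fst)
  if (length(pair_i) != ncol(fst) || length(pair_j) != ncol(fst)) {
    stop("pair_i/pair_j must name the columns of fst")
  }
  sel <- which(pair_i == focal | pair_j == focal)
  if (!length(sel)) stop("focal pool appears in no pair: ", focal)
  z <- matrix(NA_real_, nrow(fst), length(sel))
  for (k in seq_along(sel)) {
    v <- fst[, sel[k]]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      stop(sprintf("fewer than 2 windows with defined FST for pair %s-%s",
                   pair_i[sel[k]], pair_j[sel[k]]))
    }
    mu <- mean(v[ok])
    sigma <- pop_sd(v[ok])
    if (sigma == 0) {
      stop(sprintf("sd of window FST is zero for pair %s-%s",
                   pair_i[sel[k]], pair_j[sel[k]]))
    }
    z[, k] <- (v - mu) / sigma
  }
  rowSums(z)  # NA whenever any pair involving the focal pool is NA
}

#' Score sliding windows: Hp, ZHp, pairwise FST and di
#'
#' The central scoring step of the scan. For every window and pool it
#' accumulates major/minor read sums and pooled heterozygosity Hp, Z-scores
#' Hp per pool into ZHp, computes window FST for every pool pair
#' (ratio-of-averages over informative SNPs) and the di statistic for each
#' focal pool. Windows with fewer than `min_snps` member SNPs are excluded:
#' their Hp/ZHp/FST/di are `NA` and they enter none of the standardisation
#' moments. All computations are deterministic.
#'
#' @param snps A [as_snp_table()] object.
#' @param frame A [make_windows()] frame; SNPs are assigned automatically
#'   if [assign_snps()] has not been run.
#' @param pools Pools to score (default: all pools in `snps`).
#' @param focal Pools for which di is computed (default: all scored pools).
#' @param min_snps Minimum member SNPs for a window to be scored
#'   (default 10); sparse windows make Hp and FST unstable.
#' @return A `window_scores` object: list with `windows`, `pools`,
#'   `n_snps`, `included`, matrices `sum_nmaj`, `sum_nmin`, `hp`, `zhp`
#'   (windows x pools), `mu_hp`, `sigma_hp`, `pairs` (data.frame
#'   `pool1`, `pool2`), `fst` (windows x pairs), `fst_mean`, `fst_sd`,
#'   and `di` (windows x focal pools).
#' @export
score_windows <- function(snps, frame, pools = pool_names(snps),
                          focal = pools, min_snps = 10) {
  stopifnot(inherits(snps, "snp_table"), inherits(frame, "window_frame"))
  if (is.null(frame$membership)) frame <- assign_snps(snps, frame)
  absent <- setdiff(c(pools, focal), pool_names(snps))
  if (length(absent)) stop("unknown pool(s): ", paste(absent, collapse = ", "))
  if (!all(focal %in% pools)) stop("focal pools must be among scored pools")

  W <- nrow(frame$windows)
  n_snps <- frame$n_snps
  included <- n_snps >= min_snps

  P <- length(pools)
  sum_nmaj <- sum_nmin <- hp <- zhp <- matrix(NA_real_, W, P,
                                              dimnames = list(NULL, pools))
  mu_hp <- sigma_hp <- stats::setNames(numeric(P), pools)
  for (p in pools) {
    s <- window_allele_sums(snps, frame, p)
    sum_nmaj[, p] <- s$sum_nmaj
    sum_nmin[, p] <- s$sum_nmin
    h <- pooled_heterozygosity(s$sum_nmaj, s$sum_nmin)
    h[!included] <- NA_real_
    hp[, p] <- h
    z <- z_transform(h)
    zhp[, p] <- z
    mu_hp[p] <- attr(z, "mu")
    sigma_hp[p] <- attr(z, "sigma")
  }

  freq <- alt_freqs(snps)
  m <- frame$membership
  pair_idx <- if (P >= 2L) utils::combn(pools, 2L) else matrix(character(0), 2L, 0L)
  K <- ncol(pair_idx)
  pairs <- data.frame(pool1 = pair_idx[1L, ], pool2 = pair_idx[2L, ],
                      stringsAsFactors = FALSE)
  fst <- matrix(NA_real_, W, K)
  colnames(fst) <- if (K) paste(pairs$pool1, pairs$pool2, sep = "|") else character(0)
  agg <- function(v) {
    out <- numeric(W)
    if (nrow(m)) {
      s <- rowsum(v[m$snp], m$window)
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
  for (k in seq_len(K)) {
    comp <- snp_fst(freq[, pairs$pool1[k]], freq[, pairs$pool2[k]])
    inf <- !is.na(comp$den) & !is.na(comp$num) & comp$den > 0
    num_w <- agg(ifelse(inf, comp$num, 0))
    den_w <- agg(ifelse(inf, comp$den, 0))
    v <- num_w / den_w
    v[den_w == 0] <- NA_real_
    v[!included] <- NA_real_
    fst[, k] <- v
  }
  fst_mean <- apply(fst, 2L, function(v) mean(v[!is.na(v)]))
  fst_sd <- apply(fst, 2L, function(v) pop_sd(v[!is.na(v)]))

  di <- matrix(NA_real_, W, length(focal), dimnames = list(NULL, focal))
  for (f in focal) {
    di[, f] <- di_statistic(fst, pairs$pool1, pairs$pool2, f)
  }

  structure(list(windows = frame$windows, window_size = frame$window_size,
                 step = frame$step, pools = pools, n_snps = n_snps,
                 included = included, min_snps = min_snps,
                 sum_nmaj = sum_nmaj, sum_nmin = sum_nmin,
                 hp = hp, zhp = zhp, mu_hp = mu_hp, sigma_hp = sigma_hp,
                 pairs = pairs, fst = fst, fst_mean = fst_mean,
                 fst_sd = fst_sd, di = di, focal = focal),
            class = "window_scores")
}

#' @export
print.window_scores <- function(x, ...) {
  cat(sprintf("window_scores: %d windows (%d included, min_snps = %g), %d pools, %d pairs\n",
              nrow(x$windows), sum(x$included), x$min_snps,
              length(x$pools), nrow(x$pairs)))
  cat(sprintf("mean Hp per pool: %s\n",
              paste(sprintf("%s=%.4f", x$pools, x$mu_hp), collapse = ", ")))
  invisible(x)
}
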
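#' Configure the pool-seq simulator
#'
#' The simulator emulates pooled resequencing of several populations that
#' diverged from a shared ancestor by drift, with selective sweeps planted
#' in chosen pools at chosen intervals. Defaults mirror an eight-breed
#' pooled resequencing design: 8 pools at ~10x mean depth, one SNP per
#' ~1.5 kb (about 100 SNPs per 150-kb window), ancestral allele
#' frequencies uniform on (0.05, 0.95) (rare alleles are largely removed
#' by SNP calling), and a Balding-Nichols drift parameter F = 0.1 per
#' pool.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_pools Number of pools (default 8).
#' @param pool_names Pool names (default `pool01`, `pool02`, ...).
#' @param snp_density Expected SNPs per bp (default 1/1500).
#' @param drift Balding-Nichols F per pool, in (0, 1); recycled
#'   (default 0.1).
#' @param ancestral_range Range of the uniform ancestral allele frequency
#'   (default `c(0.05, 0.95)`).
#' @param mean_depth Mean sequencing depth per pool (Poisson; recycled;
#'   default 10).
#' @param sweeps Optional data.frame of planted sweeps: `chrom`, `start`,
#'   `end` (0-based half-open bp), `pool`, `s` (intensity in [0, 1]).
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @param emit_true_freqs If `TRUE`, emit counts that encode the exact
#'   post-sweep allele frequencies (scaled by `freq_scale`) instead of
#'   sampling reads; also return the frequency matrix.
#' @param freq_scale Total count used per pool and SNP when
#'   `emit_true_freqs` (default 10000).
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths, n_pools = 8, pool_names = NULL,
                       snp_density = 1 / 1500, drift = 0.1,
                       ancestral_range = c(0.05, 0.95), mean_depth = 10,
                       sweeps = NULL, seed = 1, emit_true_freqs = FALSE,
                       freq_scale = 10000L) {
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (is.null(pool_names)) pool_names <- sprintf("pool%02d", seq_len(n_pools))
  if (length(pool_names) != n_pools) stop("pool_names must have length n_pools")
  drift <- rep_len(drift, n_pools)
  mean_depth <- rep_len(mean_depth, n_pools)
  if (any(drift <= 0) || any(drift >= 1)) stop("drift F must lie in (0, 1)")
  if (snp_density <= 0) stop("snp_density must be positive")
  if (length(ancestral_range) != 2L || ancestral_range[1L] <= 0 ||
      ancestral_range[2L] >= 1 || ancestral_range[1L] >= ancestral_range[2L]) {
    stop("ancestral_range must be within (0, 1) with low < high")
  }
  if (!is.null(sweeps)) {
    sweeps <- as.data.frame(sweeps, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "pool", "s")
    if (!all(need %in% names(sweeps))) {
      stop("sweeps needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(sweeps$chrom %in% names(chrom_lengths))) {
      stop("sweep on unknown chromosome")
    }
    bad <- sweeps$start < 0 | sweeps$end > chrom_lengths[sweeps$chrom] |
      sweeps$start >= sweeps$end
    if (any(bad)) stop("sweep interval out of chromosome bounds at row ",
                       which(bad)[1L])
    if (any(sweeps$s < 0 | sweeps$s > 1)) stop("sweep intensity s must lie in [0, 1]")
    if (!all(sweeps$pool %in% pool_names)) stop("sweep in unknown pool")
  }
  structure(list(chrom_lengths = chrom_lengths, n_pools = n_pools,
                 pool_names = pool_names, snp_density = snp_density,
                 drift = stats::setNames(drift, pool_names),
                 ancestral_range = ancestral_range,
                 mean_depth = stats::setNames(mean_depth, pool_names),
                 sweeps = sweeps, seed = as.integer(seed),
                 emit_true_freqs = isTRUE(emit_true_freqs),
                 freq_scale = as.integer(freq_scale)),
            class = "sim_config")
}

#' Balding-Nichols population allele frequency
#'
#' Draws a descendant-population allele frequency around ancestral
#' frequency `p` under drift `F`: `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)`,
#' which has mean `p` and variance `F p (1 - p)`. Boundary frequencies
#' (`p` of 0 or 1) are returned unchanged.
#'
#' @param p Ancestral allele frequency (vectorised).
#' @param F_drift Drift parameter in (0, 1).
#' @return Numeric vector of population frequencies.
#' @export
balding_nichols_freq <- function(p, F_drift) {
  if (F_drift <= 0 || F_drift >= 1) stop("F must lie in (0, 1)")
  out <- p
  inner <- p > 0 & p < 1
  k <- (1 - F_drift) / F_drift
  out[inner] <- stats::rbeta(sum(inner), p[inner] * k, (1 - p[inner]) * k)
  out
}

#' Apply a selective sweep to a focal-pool frequency
#'
#' Pulls the frequency a fraction `s` of the way toward the nearer
#' fixation boundary: `(1 - s) p + s round(p)`, with frequencies exactly
#' at 0.5 pulled toward 1. `s = 0` leaves the frequency unchanged;
#' `s = 1` fixes it. This is a deterministic frequency pull, giving exact
#' control of effect size, not a coalescent sweep model.
#'
#' @param p Pre-sweep frequency in [0, 1] (vectorised).
#' @param s Sweep intensity in [0, 1].
#' @return Post-sweep frequency.
#' @export
apply_sweep <- function(p, s) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  target <- ifelse(p >= 0.5, 1, 0)
  (1 - s) * p + s * target
}

#' Sample pooled read counts at a SNP
#'
#' Depth is Poisson with the pool's mean; alternate reads are Binomial in
#' the depth at the population alternate-allele frequency.
#'
#' @param p Alternate allele frequency (vectorised).
#' @param mean_depth Mean depth.
#' @return List with integer vectors `ref` and `alt`.
#' @export
sample_reads <- function(p, mean_depth) {
  n <- length(p)
  d <- stats::rpois(n, mean_depth)
  alt <- stats::rbinom(n, d, p)
  list(ref = d - alt, alt = alt)
}

#' Simulate a multi-pool SNP dataset with planted sweeps
#'
#' Places SNPs uniformly at the configured density (Poisson number per
#' chromosome, distinct positions), draws an ancestral frequency per SNP,
#' derives per-pool frequencies by the Balding-Nichols model, applies each
#' configured sweep to its focal pool inside its interval, and samples
#' pooled read counts (or encodes exact frequencies when
#' `emit_true_freqs`). Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `snps` (a [as_snp_table()]), `truth` (an
#'   [interval_set()] of planted sweeps, names `pool;s=<s>`; empty when no
#'   sweeps), `true_freqs` (matrix, only when `emit_true_freqs`), and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  pos_l <- list()
  chrom_l <- list()
  for (ch in chroms) {
    L <- config$chrom_lengths[[ch]]
    n <- stats::rpois(1L, L * config$snp_density)
    n <- min(n, L)
    pos_l[[ch]] <- sort(sample.int(L, n))
    chrom_l[[ch]] <- rep(ch, n)
  }
  pos <- unlist(pos_l, use.names = FALSE)
  chrom <- unlist(chrom_l, use.names = FALSE)
  n <- length(pos)

  p_anc <- stats::runif(n, config$ancestral_range[1L], config$ancestral_range[2L])
  freq <- matrix(NA_real_, n, config$n_pools,
                 dimnames = list(NULL, config$pool_names))
  for (p in config$pool_names) {
    freq[, p] <- balding_nichols_freq(p_anc, config$drift[[p]])
  }
  if (!is.null(config$sweeps)) {
    for (i in seq_len(nrow(config$sweeps))) {
      sw <- config$sweeps[i, ]
      idx <- which(chrom == sw$chrom & (pos - 1L) >= sw$start &
                     (pos - 1L) < sw$end)
      freq[idx, sw$pool] <- apply_sweep(freq[idx, sw$pool], sw$s)
    }
  }

  ref_i <- sample.int(4L, n, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  bases <- c("A", "C", "G", "T")
  df <- data.frame(chrom = chrom, pos = pos, ref = bases[ref_i],
                   alt = bases[alt_i], stringsAsFactors = FALSE)
  for (p in config$pool_names) {
    if (config$emit_true_freqs) {
      ac <- as.integer(round(freq[, p] * config$freq_scale))
      rc <- config$freq_scale - ac
    } else {
      r <- sample_reads(freq[, p], config$mean_depth[[p]])
      ac <- r$alt
      rc <- r$ref
    }
    df[[paste0(p, "_ref")]] <- rc
    df[[paste0(p, "_alt")]] <- ac
  }
  snps <- as_snp_table(df, pools = config$pool_names)

  truth <- if (!is.null(config$sweeps) && nrow(config$sweeps)) {
    interval_set(config$sweeps$chrom, config$sweeps$start, config$sweeps$end,
                 sprintf("%s;s=%g", config$sweeps$pool, config$sweeps$s))
  } else {
    interval_set(character(0), numeric(0), numeric(0))
  }
  out <- list(snps = snps, truth = truth, config = config)
  if (config$emit_true_freqs) out$true_freqs <- freq
  out
}
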
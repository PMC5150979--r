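# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# Random snp_table with the given pools; counts uniform in 0..max_count.
random_snp_table <- function(n = 50, pools = c("A", "B"), chroms = "chr1",
                             max_pos = 1e6, max_count = 30, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(max_pos, n))
  chrom <- sort(sample(chroms, n, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  df <- data.frame(chrom = chrom, pos = pos, ref = bases[ref_i],
                   alt = bases[alt_i], stringsAsFactors = FALSE)
  for (p in pools) {
    df[[paste0(p, "_ref")]] <- sample.int(max_count + 1L, n, replace = TRUE) - 1L
    df[[paste0(p, "_alt")]] <- sample.int(max_count + 1L, n, replace = TRUE) - 1L
  }
  df <- df[!duplicated(df[c("chrom", "pos")]), ]
  as_snp_table(df, pools = pools)
}

# Small snp_table from explicit per-pool (ref, alt) count rows.
# counts: list of matrices n x 2, one per pool.
toy_snp_table <- function(pos, counts, pools = names(counts),
                          chrom = "chr1", ref = NULL, alt = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  df <- data.frame(chrom = rep(chrom, length.out = n), pos = pos,
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  for (p in pools) {
    df[[paste0(p, "_ref")]] <- counts[[p]][, 1L]
    df[[paste0(p, "_alt")]] <- counts[[p]][, 2L]
  }
  as_snp_table(df, pools = pools)
}

# Write a minimal VCF 4.2 with per-sample AD carrying the snp_table counts.
# extra_records: character vector of extra VCF body lines to append.
write_toy_vcf <- function(path, snps, extra_records = character(0)) {
  pools <- pool_names(snps)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(snps)), function(i) {
    ad <- vapply(pools, function(p) {
      sprintf("./.:%d,%d", snps[[paste0(p, "_ref")]][i],
              snps[[paste0(p, "_alt")]][i])
    }, character(1))
    paste(c(snps$chrom[i], snps$pos[i], ".", snps$ref[i], snps$alt[i], ".",
            "PASS", ".", "GT:AD", ad), collapse = "\t")
  }, character(1))
  writeLines(c(header, body, extra_records), path)
  invisible(path)
}

# Simulated dataset with planted sweeps used by scan-level tests: 4 pools,
# 10 Mb, 3 sweeps of 300 kb at s = 0.95 in pool01.
scan_fixture <- function(seed = 42) {
  sweeps <- data.frame(chrom = "chr1", start = c(1e6, 4e6, 7.5e6),
                       end = c(1.3e6, 4.3e6, 7.8e6),
                       pool = "pool01", s = 0.95)
  cfg <- sim_config(c(chr1 = 1e7), n_pools = 4, mean_depth = 10,
                    seed = seed, sweeps = sweeps)
  sim <- simulate_genome(cfg)
  list(cfg = cfg, sim = sim, sweeps = sweeps)
}

# Brute-force window membership: indices of SNPs with start <= pos-1 < end.
brute_members <- function(snps, chrom, start, end) {
  which(snps$chrom == chrom & (snps$pos - 1) >= start & (snps$pos - 1) < end)
}

# 1 bp interval overlap test, 0-based half-open.
overlaps <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2
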
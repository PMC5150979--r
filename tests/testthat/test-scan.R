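# Scan-level behaviour on a simulated genome with three planted sweeps
# (4 pools, 10 Mb, s = 0.95 in pool01). With 3 x 300 kb sweeps on 10 Mb,
# ~12% of windows are swept, so selection thresholds matched to that design
# (ZHp <= -2, di quantile 0.88) are used; the published-scale defaults
# (-4 / 0.99) assume a genome where sweeps are a negligible fraction.

test_that("planted sweeps dominate the extremes of ZHp and di", {
  fx <- scan_fixture()
  scan <- sweep_scan(fx$sim$snps, fx$cfg$chrom_lengths, focal = "pool01",
                     zhp_threshold = -2, di_quantile = 0.88)
  s <- scan$scores
  w <- s$windows
  tr <- fx$sim$truth
  swept <- vapply(seq_len(nrow(w)), function(i)
    any(overlaps(w$start[i], w$end[i], tr$start, tr$end)), logical(1))
  low5 <- order(s$zhp[, "pool01"])[1:5]
  top5 <- order(-s$di[, "pool01"])[1:5]
  expect_true(all(swept[low5]))
  expect_true(all(swept[top5]))
})

test_that("the dual-criterion scan recovers planted sweeps at design-matched thresholds", {
  fx <- scan_fixture()
  scan <- sweep_scan(fx$sim$snps, fx$cfg$chrom_lengths, focal = "pool01",
                     zhp_threshold = -2, di_quantile = 0.88)
  both <- scan$loci$pool01$both
  tr <- fx$sim$truth
  recovered <- vapply(seq_len(nrow(tr)), function(i)
    any(overlaps(tr$start[i], tr$end[i], both$start, both$end)), logical(1))
  false_loci <- vapply(seq_len(nrow(both)), function(i)
    !any(overlaps(both$start[i], both$end[i], tr$start, tr$end)), logical(1))
  expect_equal(sum(recovered), 3L)
  expect_equal(sum(false_loci), 0L)
  expect_true(all(both$min_zhp <= -2))
})

test_that("sweep windows show strongly reduced focal heterozygosity", {
  fx <- scan_fixture()
  scores <- score_windows(fx$sim$snps, make_windows(fx$cfg$chrom_lengths),
                          focal = "pool01")
  w <- scores$windows
  tr <- fx$sim$truth
  fully <- vapply(seq_len(nrow(w)), function(i)
    any(tr$start <= w$start[i] & w$end[i] <= tr$end), logical(1))
  swept <- vapply(seq_len(nrow(w)), function(i)
    any(overlaps(w$start[i], w$end[i], tr$start, tr$end)), logical(1))
  neutral_median <- stats::median(scores$hp[!swept, "pool01"], na.rm = TRUE)
  expect_true(all(scores$hp[fully, "pool01"] <= 0.2 * neutral_median))
  # non-focal pools are unaffected by the sweep
  other_median <- stats::median(scores$hp[!swept, "pool02"], na.rm = TRUE)
  expect_gt(stats::median(scores$hp[fully, "pool02"], na.rm = TRUE),
            0.5 * other_median)
})

test_that("summary and print report the scan consistently", {
  fx <- scan_fixture()
  scan <- sweep_scan(fx$sim$snps, fx$cfg$chrom_lengths, focal = "pool01",
                     zhp_threshold = -2, di_quantile = 0.88)
  sm <- summary(scan)
  expect_equal(sm$per_focal$pool, "pool01")
  expect_equal(sm$per_focal$n_both_loci, nrow(scan$loci$pool01$both))
  expect_equal(sm$per_focal$di_cutoff, scan$loci$pool01$di_cutoff)
  expect_output(print(scan), "dual-criterion loci")
  expect_output(print(sm), "Selection: ZHp <=")
  # plotting returns invisibly without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(scan, statistic = "zhp"))
})

test_that("run_simulate writes reproducible outputs and run_scan consumes them", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(chrom_lengths = list(chr1 = 2e6), n_pools = 3, seed = 5,
                 sweeps = data.frame(chrom = "chr1", start = 5e5, end = 8e5,
                                     pool = "pool01", s = 0.95))
  config$out_dir <- out1
  suppressMessages(p1 <- run_simulate(config))
  expect_true(all(file.exists(p1)))
  config$out_dir <- out2
  suppressMessages(p2 <- run_simulate(config))
  expect_identical(readLines(p1[["counts"]]), readLines(p2[["counts"]]))
  expect_identical(readLines(p1[["truth"]]), readLines(p2[["truth"]]))

  genes_bed <- file.path(out1, "genes.bed")
  writeLines("chr1\t600000\t650000\tGENE1", genes_bed)
  scan_cfg <- list(counts = p1[["counts"]],
                   chrom_lengths = list(chr1 = 2e6),
                   focal = "pool01", min_snps = 5,
                   zhp_threshold = -2, di_quantile = 0.88,
                   genes_bed = genes_bed, out_dir = file.path(out1, "scan"))
  msgs <- capture_messages(scan <- run_scan(scan_cfg))
  expect_true(any(grepl("realised di cutoff", msgs)))
  expect_true(file.exists(file.path(out1, "scan", "window_scores.tsv")))
  expect_true(file.exists(file.path(out1, "scan", "loci_pool01.tsv")))
  expect_true(file.exists(file.path(out1, "scan", "breed_specific_pool01.tsv")))
  expect_true(file.exists(file.path(out1, "scan", "scan_config.json")))
  expect_s3_class(scan, "sweep_scan")
})

test_that("run_summaries writes per-pool spectra and rejects unknown pools", {
  out <- withr::local_tempdir()
  sim_cfg <- list(chrom_lengths = list(chr1 = 5e5), n_pools = 2, seed = 3,
                  out_dir = out)
  suppressMessages(paths <- run_simulate(sim_cfg))
  sm_cfg <- list(counts = paths[["counts"]], out_dir = out)
  suppressMessages(got <- run_summaries(sm_cfg))
  spec <- utils::read.delim(got[["spectrum"]], stringsAsFactors = FALSE)
  expect_equal(sort(unique(spec$pool)), c("pool01", "pool02"))
  expect_equal(nrow(spec), 20L)
  snps <- read_count_table(paths[["counts"]])
  depth <- pool_counts(snps, "ref")[, "pool01"] + pool_counts(snps, "alt")[, "pool01"]
  expect_equal(sum(spec$count[spec$pool == "pool01"]), sum(depth > 0))
  expect_error(suppressMessages(
    run_summaries(list(counts = paths[["counts"]], pools = "nope"))), "nope")
})
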
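# Minimal window_scores stub for selection-rule tests: only the fields
# select_windows() consults.
stub_scores <- function(zhp, di) {
  structure(list(zhp = cbind(A = zhp), di = cbind(A = di)),
            class = "window_scores")
}

test_that("selection flags use an inclusive ZHp boundary and an interpolated di quantile", {
  zhp <- c(-4.0, -3.99, -5, 0)
  di <- c(1, 2, 3, 4)
  fl <- select_windows(stub_scores(zhp, di), "A")
  expect_equal(fl$low_zhp, c(TRUE, FALSE, TRUE, FALSE))

  # 200 windows with di = 1..200: the 99th percentile interpolates to 198.01
  fl2 <- select_windows(stub_scores(rep(0, 200), 1:200), "A")
  expect_equal(fl2$di_cutoff, 198.01)
  expect_equal(which(fl2$high_di), c(199L, 200L))

  fl3 <- select_windows(stub_scores(rep(c(-1, -2), 100), 1:200), "A")
  expect_equal(sum(fl3$low_zhp), 0L)
})

test_that("raising the di quantile never increases the flagged set", {
  set.seed(31)
  di <- stats::rnorm(500)
  zhp <- stats::rnorm(500)
  previous <- Inf
  for (q in c(0.90, 0.95, 0.99, 0.999)) {
    n <- sum(select_windows(stub_scores(zhp, di), "A", di_quantile = q)$high_di)
    expect_lte(n, previous)
    previous <- n
  }
})

test_that("flagged windows merge into disjoint loci with aggregated scores", {
  loci <- merge_windows(chrom = c("chr1", "chr1"),
                        start = c(0, 75000), end = c(150000, 225000),
                        zhp = c(-4.5, -5.0))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 0)
  expect_equal(loci$end, 225000)
  expect_equal(loci$min_zhp, -5.0)
  expect_equal(loci$n_windows, 2L)

  apart <- merge_windows(chrom = c("chr1", "chr1"),
                         start = c(0, 300000), end = c(150000, 450000))
  expect_equal(nrow(apart), 2L)

  chained <- merge_windows(chrom = rep("chr1", 3),
                           start = c(0, 75000, 150000),
                           end = c(150000, 225000, 300000),
                           zhp = c(-4.2, -5.2, -4.1), di = c(3, 9, 5))
  expect_equal(nrow(chained), 1L)
  expect_equal(chained$min_zhp, -5.2)
  expect_equal(chained$max_di, 9)

  # disjointness + footprint preservation on a random flag set
  set.seed(13)
  starts <- sort(sample(0:100, 25)) * 75000
  m <- merge_windows(rep("chr1", 25), starts, starts + 150000)
  expect_true(all(m$start[-1] > utils::head(m$end, -1)))  # disjoint, gap > 0
  covered <- unique(unlist(mapply(function(s, e) seq(s, e - 75000, by = 75000),
                                  starts, starts + 150000, SIMPLIFY = FALSE)))
  expect_equal(sum(m$end - m$start),
               length(covered) * 75000)
})

test_that("locus intersection is symmetric and splits spanning loci", {
  a <- merge_windows("chr1", 0, 225000, zhp = -5)
  b <- merge_windows("chr1", 150000, 300000, di = 12)
  ab <- intersect_loci(a, b)
  expect_equal(ab[c("start", "end")], data.frame(start = 150000, end = 225000))
  expect_equal(ab$criterion, "both")
  expect_equal(ab$min_zhp, -5)
  expect_equal(ab$max_di, 12)
  ba <- intersect_loci(b, a)
  expect_equal(ba[c("chrom", "start", "end")], ab[c("chrom", "start", "end")])

  expect_equal(nrow(intersect_loci(a, merge_windows("chr2", 0, 1000, di = 1))), 0L)

  # one di locus spanning two separate zhp loci -> two dual-criterion loci
  zhp2 <- merge_windows(c("chr1", "chr1"), c(0, 400000), c(150000, 550000),
                        zhp = c(-4.5, -6))
  di1 <- merge_windows("chr1", 100000, 450000, di = 20)
  both <- intersect_loci(zhp2, di1)
  expect_equal(nrow(both), 2L)
  expect_equal(both$start, c(100000, 400000))
  expect_equal(both$end, c(150000, 450000))
})

test_that("gene annotation respects the half-open overlap convention", {
  loci <- data.frame(chrom = "chr1", start = 150000, end = 225000,
                     min_zhp = -5, max_di = 10, stringsAsFactors = FALSE)
  genes <- interval_set(rep("chr1", 3), c(160000, 225000, 140000),
                        c(170000, 230000, 150001), c("IN", "ABUT", "EDGE"))
  out <- annotate_loci(loci, genes)
  # ABUT starts exactly at the locus end: no overlap under half-open intervals
  expect_equal(out$genes, "EDGE,IN")
  loci2 <- data.frame(chrom = "chr1", start = 0, end = 100, stringsAsFactors = FALSE)
  expect_equal(annotate_loci(loci2, genes)$genes, "")
})

test_that("breed-specific SNPs require focal-alt major, others ref major, and gene proximity", {
  # 6 SNPs, 3 pools; gene body [10000, 20000)
  pos <- c(5000L, 9000L, 9001L, 15000L, 16000L, 21001L)
  counts <- list(
    F = cbind(c(3L, 3L, 3L, 3L, 6L, 3L), c(9L, 9L, 9L, 9L, 6L, 9L)),
    O1 = cbind(c(10L, 10L, 10L, 10L, 10L, 10L), c(2L, 2L, 2L, 2L, 2L, 2L)),
    O2 = cbind(c(8L, 8L, 8L, 8L, 8L, 3L), c(1L, 1L, 1L, 1L, 9L, 1L))
  )
  snps <- toy_snp_table(pos, counts)
  gene <- interval_set("chr1", 10000, 20000, "G1")
  got <- breed_specific_snps(snps, "F", gene, flank = 1000)
  # pos 5000: outside flank; 9000: 1001 bp upstream of start (0-based 8999 < 9000), out;
  # 9001: exactly 1000 bp upstream, in; 15000: inside; 16000: focal at 0.5, not major;
  # also O2 is alt-major there; 21001: 0-based 21000 = end+flank-0 -> inside? end+flank=21000,
  # half-open so 0-based 21000 is excluded.
  expect_equal(got$pos, c(9001L, 15000L))
  expect_equal(got$genes, c("G1", "G1"))

  # conserved-region restriction
  cons <- interval_set("chr1", 14000, 15500, "cons")
  got2 <- breed_specific_snps(snps, "F", gene, flank = 1000, conserved = cons)
  expect_equal(got2$pos, 15000L)
  expect_error(breed_specific_snps(snps, "nope", gene), "absent")
})
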
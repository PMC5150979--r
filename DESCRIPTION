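Package: poolscan
Title: Selective-Sweep Scans from Pooled Whole-Genome Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects selection signatures from pooled resequencing (pool-seq)
    allele read counts. Computes pooled heterozygosity (Hp) and its
    Z-transform (ZHp) in sliding windows along autosomes, pairwise window
    FST and the di lineage-differentiation statistic, and calls candidate
    selective loci under a dual criterion (extremely low ZHp and top-quantile
    di), with gene annotation and breed-specific SNP calling. Includes SNP
    filtering and descriptive summaries (minor-allele-frequency spectra,
    heterozygous/homozygous composition) and a Balding-Nichols pool-seq
    simulator that plants sweeps of known location and intensity so the whole
    scan can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
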
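---
title: "Detecting selective sweeps from pooled sequencing: methods and design"
author: "poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from pooled sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem

Pooled whole-genome resequencing (pool-seq) sequences DNA pooled from many
individuals of one population, so the data are per-population allele *read
counts*, not genotypes. Domesticated populations under strong artificial or
natural selection carry selective sweeps: genomic intervals where a favoured
allele rose toward fixation, depressing local diversity in the selected
population and inflating its differentiation from related populations.
`poolscan` detects such intervals from multi-pool SNP count data by combining
two complementary window statistics and calling candidate loci where both are
extreme.

## Statistics

### Pooled heterozygosity and its Z-transform

For each sliding window and pool, let $\Sigma n_{MAJ}$ and $\Sigma n_{MIN}$
be the summed read counts of the most and least observed allele over the
window's SNPs, with major/minor polarity decided per SNP from that pool's own
counts. The pooled heterozygosity is

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ}+\Sigma n_{MIN})^2},$$

which lies in $[0, 0.5]$ and is invariant to rescaling both sums (sequencing
depth cancels). Within one pool, window values are standardised into

$$ZH_p = \frac{H_p - \mu_{H_p}}{\sigma_{H_p}},$$

with $\mu_{H_p}$ and $\sigma_{H_p}$ the mean and standard deviation over all
scored windows of that pool. Sweeps appear as strongly negative $ZH_p$.

### Window FST and the di statistic

For each pool pair and SNP, allele frequencies $p_1, p_2$ are the alternate
read fractions; with $\bar p = (p_1+p_2)/2$, the Nei/Hudson-style components
are $H_T = 2\bar p(1-\bar p)$ and $H_S = p_1(1-p_1)+p_2(1-p_2)$. Window FST
is the ratio of averages $\sum(H_T-H_S)/\sum H_T$ over the window's
informative SNPs ($H_T>0$, both pools covered). Ratio-of-averages is the
standard recommendation for combining FST across sites; per-SNP
ratio averaging is biased for low-heterozygosity SNPs. Small negative window
values are retained, since clamping at zero would bias the genome-wide means
used next.

For focal pool $i$ and window $w$,

$$d_i(w) = \sum_{j \ne i} \frac{F_{ST}^{ij}(w) - \mathbb{E}[F_{ST}^{ij}]}{\mathrm{sd}[F_{ST}^{ij}]},$$

with the expectation and standard deviation per pair taken across all scored
windows. Large $d_i$ marks windows where the focal lineage is unusually
diverged from every other pool simultaneously — the cross-population
signature of a lineage-specific sweep.

### Selection rule and loci

A window is flagged when $ZH_p \le$ `zhp_threshold` (default $-4$,
inclusive) or when $d_i$ reaches the `di_quantile` quantile (default 0.99,
the "top 1%") of defined $d_i$ values. Overlapping or book-ended flagged
windows merge into loci (most negative member $ZH_p$ and largest member
$d_i$ retained); base-pair intersections of low-$ZH_p$ and high-$d_i$ loci
are the dual-criterion candidates. Genes are attached by $\ge 1$ bp overlap
under half-open interval semantics.

## Conventions and numerical choices

* **Coordinates.** Internally 0-based half-open everywhere (BED-compatible);
  VCF positions are converted on input, and all emitted BED/TSV intervals
  are 0-based half-open.
* **Windows.** 150-kb windows stepping 75 kb (half-window overlap, the usual
  design for this family of scans; both configurable). Windows start at every
  multiple of the step up to `length - step` and are truncated at the
  chromosome end, so a chromosome shorter than one window still gets one
  window. Only listed autosomes are windowed: sex chromosomes have different
  effective population size and selective exposure.
* **Sparse windows.** Windows with fewer than `min_snps` member SNPs
  (default 10) are reported `NA` and excluded from $\mu$, $\sigma$, the
  FST moments, quantiles and selection: with a handful of SNPs both $H_p$
  and window FST are dominated by sampling noise.
* **Standard deviations.** Population (n-denominator) form everywhere
  ($ZH_p$ and per-pair FST standardisation), one consistent convention.
* **Quantiles.** Linear interpolation between order statistics
  (`stats::quantile` type 7); the realised cutoff is always reported so
  other conventions can be audited.
* **Boundaries.** $ZH_p$ threshold is inclusive ($\le -4$); ties at the di
  cutoff are included; gene flanks for breed-specific SNPs are inclusive at
  exactly `flank` bp.
* **Zero depth.** SNPs with zero reads in a pool stay in the table but
  contribute nothing to that pool's window sums, pair FST (the SNP is
  uninformative for pairs involving that pool) or summaries, and cannot
  veto breed-specificity.
* **Degenerate inputs.** A constant $H_p$ series or a zero-variance FST
  pair is an error (naming the pair), not a silent `NaN`.

## Breed-specific SNPs

A SNP is breed-specific for a focal pool when its major allele there is the
alternate allele (alternate read frequency $> 0.5$ by default — pools are
rarely fully fixed, so fixation is not required), every other covered pool
has the reference allele as major, and the site lies within a gene interval
extended by 1000 bp (configurable) on both sides; an optional
conserved-region interval set restricts hits further.

## Count-level SNP filtering

Variant-calling hygiene is approximated at the count level: pools below a
minimum depth (default 4) at a site contribute nothing there; a SNP needs at
least one pool with $\ge 3$ alternate reads; an optional pooled-MAF floor
removes rare variants. The classical read-level criterion of several
alternate reads with *distinct start sites* cannot be evaluated from counts;
the alt-read-count threshold is its count-level surrogate, and users with
BAM-level evidence should pre-filter upstream.

## The simulator

`sim_config()`/`simulate_genome()` generate multi-pool count data with known
ground truth. Per SNP, an ancestral frequency is drawn uniformly on
(0.05, 0.95) — SNP calling removes most rare alleles, so the ancestral
spectrum is bounded away from 0 and 1 — and each pool's frequency is a
Balding–Nichols draw, $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, with mean
$p$ and variance $Fp(1-p)$ ($F = 0.1$ per pool by default). Planted sweeps
pull the focal pool's frequency a fraction $s$ of the way to the nearer
fixation boundary (ties at 0.5 go to 1); this deterministic pull gives exact
control of effect size, unlike a coalescent simulation. Read counts are
Poisson depth (mean 10 per pool, the scale of a medium-coverage pooled
design of ~8 breeds) with Binomial allele sampling; `emit_true_freqs`
bypasses read sampling to expose exact frequencies for calibration work.
Default density is one SNP per 1.5 kb, about 100 SNPs per 150-kb window.

Under this model the two-deme genome-wide ratio-of-averages FST has the
closed form $\frac{F/2}{1-F/2}$ (from $\mathbb{E}[H_S] = 2p(1-p)(1-F)$ and
$\mathbb{E}[H_T] = 2p(1-p)(1-F/2)$), which the test suite verifies to
$\pm 0.005$ at $F = 0.1$.

What the simulator does **not** emulate: linkage disequilibrium and local
coalescent structure (SNPs are independent given the ancestral frequency),
correlated breed history (all pools drift independently from one ancestor;
real breeds cluster), sequencing error, mapping or reference bias, and
indels. Passing tests therefore demonstrate the statistical machinery on an
idealised neutral-plus-sweep model, not robustness to those artefacts.

## Thresholds and genome scale

The defaults $ZH_p \le -4$ and top-1% $d_i$ are calibrated for genome-scale
scans (tens of thousands of windows) in which swept windows are a negligible
fraction, so the genome-wide $\mu$ and $\sigma$ are essentially neutral.
On small simulated genomes where sweeps occupy a visible fraction $\pi$ of
windows, both statistics saturate: swept windows themselves drag $\mu$ down
and inflate $\sigma$, capping the most negative attainable Z-score near
$-\sqrt{(1-\pi)/\pi}$ (about $-2.6$ at $\pi = 0.125$), and a top-1% rule on
a few hundred windows can flag only a handful. Benchmark analyses in this
package therefore use *design-matched* thresholds derived from the planted
sweep fraction — e.g. with 12.5% of windows swept, $ZH_p \le -2$ and
`di_quantile = 0.90` — under which the scan recovers 10/10 planted sweeps
with no false loci on the benchmark configuration (8 pools, one 30-Mb
chromosome, ten 300-kb sweeps at $s = 0.95$, mean depth 10). Rank-based
checks (the most extreme windows all lie inside planted sweeps) back this
independently of any threshold.

## Problem sizes used in the test suite

Scan-level tests use a 10-Mb, 4-pool genome with three planted sweeps;
oracle equivalence uses ~1000 windows of 15 kb on a 7.6-Mb chromosome;
simulator calibration uses ~110,000 SNPs on a 165-Mb chromosome with exact
frequencies; the neutral $ZH_p$ check uses 560 windows; and the benchmark
recovery run uses the 30-Mb, 8-pool configuration above. These sizes were
chosen so every property that scales (moment identities, calibration,
recovery) is measured with comfortable statistical resolution while the
suite stays fast.

## Known limitations

* $H_p$ weights SNPs by read depth (sums of reads), so high-depth SNPs
  dominate windows; no depth normalisation is applied.
* No correction for unequal pool sizes or finite pool sampling in FST;
  estimates are read-frequency based.
* Window counts of candidate loci depend on the (configurable) merging
  convention; published locus counts from comparable scans are not
  recoverable without the original windowing and merging choices.
* The di standardisation is across windows; standardising across SNPs is a
  plausible alternative convention and would change cutoffs.
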
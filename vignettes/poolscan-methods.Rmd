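---
title: "Methods and design notes for poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## What the package computes

poolscan analyses pooled whole-genome sequencing (pool-seq) of several
populations — the motivating setting is sets of managed honey bee
stocks, each sequenced as pools of worker heads — where the data are
per-site, per-pool nucleotide read counts (Popoolation2-style "sync"
tables) rather than individual genotypes. From those counts it
estimates:

* **within-population diversity**: windowed nucleotide diversity π and
  Watterson's θ;
* **between-population differentiation**: per-SNP classical
  F~ST~ for every pair of populations, genome-wide means,
  fixed-differentiation counts, top-quantile SNP sets, and
  population-specific SNPs;
* **population structure**: PCA of pool allele frequencies followed by
  k-means clustering with AIC scoring over k = 1–10 and elbow-based
  selection of k;
* **selection signals**: a composite selection signal (CSS) combining
  rank-transformed F~ST~ values from several population contrasts into
  one −log10 p per SNP, with outliers localized to haplotype blocks.

A synthetic-data generator produces sync tables with the statistical
structure these estimators assume, so every stage is testable end to
end without any raw sequencing data.

## Site filtering

All estimators act only on sites that pass a conservative filter set
(`filter_config()`):

* `min_coverage` (default **20 reads**): every in-scope pool must reach
  this coverage (A+T+C+G counts; N and deletion calls never count
  toward coverage).
* `min_count` (default **10 reads**): the minor allele must reach this
  count in the counts *summed across the in-scope pools* for the site to
  be a SNP. Pooling the counts matches the combined minimum-count
  semantics of the standard pool-seq tools.
* `max_cov_percentile` (default **98**): each pool's coverage
  distribution defines a cap at this percentile, so the top 2%
  highest-coverage sites are excluded. A maximum-coverage rule of this
  kind guards against collapsed repeats and copy-number variants; the
  percentile form is the standard usage pattern. It is configurable
  because "2% of the total reads" could also be read as a genome-wide
  or per-lane cap; we chose the per-pool percentile as the only
  interpretation that adapts to per-pool depth differences. With fewer
  than 100 sites the percentile is meaningless and the cap becomes
  `Inf`, with a warning.
* `min_quality` (default Phred **20**) is recorded for provenance only:
  sync tables carry no per-base qualities, so quality filtering is
  assumed to have been applied upstream when the counts were produced.

## Diversity estimators

Per-site heterozygosity uses read counts with a small-sample
correction:

$$\hat\pi_{site} = \frac{C}{C-1}\Big(1 - \sum_a f_a^2\Big),$$

with C the summed coverage and f~a~ the four base frequencies.
Monomorphic sites give exactly 0; C < 2 is undefined and the site is
skipped. Window π is the mean of per-site values over *eligible* sites
— monomorphic eligible sites contribute 0 to the numerator and 1 to
the denominator. Using the eligible-site count rather than the window
length as the denominator avoids deflating π in windows where coverage
filtering removed sites; a length denominator can be emulated by
post-multiplying.

Watterson's estimator for a window is

$$\hat\theta = \frac{S}{a_{n-1}\,L},\qquad a_{n-1} = \sum_{i=1}^{n-1}\frac1i,$$

with S the number of SNP sites, L the eligible-site count and n the
number of chromosomes sampled into the analysed pool set (24 for one
pool of 12 diploid workers; the summed value for a merged
multi-pool track). We deliberately use the pool's chromosome count, not
the read depth: the pool is the set of sampled lineages, and read-level
resampling noise is handled by the minimum-count filter. This is a
documented divergence from Popoolation's depth-aware bias corrections;
the package's estimator is defined exactly by the naive per-site oracle
in the test suite, which any reimplementation must match to 1e-12.

The locus profile partitions a locus (e.g. the *csd*
sex-determination locus) into a fixed number of equal-width
nonoverlapping windows (default 250; the last window absorbs the
division remainder) and smooths per-window π by local linear
regression (`loess`, degree 1) over window midpoints with a default
span of 0.3 — the smoothing method and span are free choices, made
once; a constant profile is returned unsmoothed so the constant-input
identity is exact. Equal width in base pairs (rather than equal SNP
count) is assumed; both the count and the span are arguments.

## Pairwise F~ST~

The per-SNP statistic is the classical π-based form

$$F_{ST} = \frac{\pi_{total}-\pi_{within}}{\pi_{total}},\qquad
\pi_{within} = \tfrac12(\hat\pi_A + \hat\pi_B),$$

with π~total~ the heterozygosity of the *summed* counts of the two
populations. Three consequences are worth stating plainly:

* Negative values occur when π~within~ exceeds π~total~ and are
  **retained**: clamping at zero would bias genome-wide means upward.
* Two pools with identical polymorphic counts give exactly
  −1/(2C−2), not 0: the C/(C−1) corrections of π~within~ (at C) and
  π~total~ (at 2C) differ. The value approaches 0 from below as
  coverage grows.
* Sites monomorphic in the combined counts (π~total~ = 0) are
  undefined and skipped.

Populations enter the scan as merged "tracks" (counts summed over their
pools), including virtual populations such as a generalized Italian
background merged from several Italian-derived stocks; eligibility is
assessed on the merged tracks' coverages, which mirrors running the
estimator on merged alignments. The genome-wide summary is the
unweighted per-SNP mean, matching the "average genome-wide" phrasing
used for such tables; a ratio-of-sums average can be computed from the
per-SNP table if preferred.

Fixed differentiation counts SNPs with F~ST~ strictly above a
threshold (default 0.65). Top-quantile sets take SNPs at or above the
empirical 1−q quantile with ties included, so an all-tied table is
returned whole. **Population-specific SNPs** are defined by a two-step
rule: a SNP is a *candidate* for population s iff it appears in the
top-q set of *every* pairwise comparison involving s, and it is
*specific* iff it is a candidate for exactly one population. The
source text for this rule ("compared among the six stocks … to
identify SNPs unique to that stock") is ambiguous; the
any-comparison-union alternative is available behind `rule = "any"`,
though with singleton-pair SNPs the union rule can never produce a
unique SNP (every pair SNP is a candidate for both of its
populations), which is itself a reason to prefer the intersection
reading.

## Structure: PCA and k-means/AIC

SNPs enter the structure analysis iff at least one population carries
the minor allele at a frequency **strictly** above 0.1 (assessed on
the merged population tracks). The pool × SNP frequency matrix is
column-mean-imputed where a pool had zero coverage, centered, and
decomposed by SVD (`prcomp`). Clustering runs on the leading
components — by default the smallest set explaining 90% of variance
(at least 2); how many components fed the original analysis is not
recorded anywhere, so this is a package default, configurable.

Each candidate k in 1–10 is scored with the spherical-Gaussian AIC

$$\mathrm{AIC}(k) = n\,d\,\ln\!\frac{W_k}{n\,d} + 2\,k\,d,$$

with W~k~ the best-of-restarts total within-cluster sum of squares
(default 25 restarts, seeded). W is floored at 1e-12 so the degenerate
k ≥ #distinct-points solution stays finite. Note that the
log-likelihood term depends only on ratios of W, so the *argmin* of
this AIC overfits any continuously noised cluster (splitting one
Gaussian cluster reduces W by a scale-free factor); that is precisely
why k is chosen by the **elbow** instead: the selected k maximizes the
discrete second difference AIC(k−1) − 2·AIC(k) + AIC(k+1), with ties
resolved to the smallest k, and fewer than three AIC points fall back
to the argmin with a warning. The analysis is k-means throughout; some
descriptions of this kind of clustering call it a KNN analysis, but
the procedure fitted and scored here is k-means.

## Composite selection signal

For each population contrast, per-SNP F~ST~ values are converted to
fractional ranks r = rank/(N+1) (average ranks for ties), which lie
strictly inside (0,1) and therefore map to finite normal quantiles
Z = Φ^−1^(r) without any clipping. Per SNP, the m contrast Z-scores
are averaged; under the null the mean of m independent standard
normals is N(0, 1/m), so

$$p = 1 - \Phi(\bar z\sqrt m), \qquad \mathrm{CSS} = -\log_{10} p.$$

The √m scaling gives an exactly calibrated null (verified by
simulation: the p distribution is uniform to a KS statistic below
0.02 at 10,000 SNPs); treating z̄ as standard normal directly would
change p but not the ranking, so outlier sets are identical either
way. No logistic smoothing is applied. Because the statistic is
rank-based, CSS is invariant under any strictly monotone transform of
each contrast's F~ST~ values — this is property-tested. By default a
SNP must have an F~ST~ value in every contrast ("complete" policy);
the "available" policy scores each SNP with its own m~i~.

Outliers are the top 0.1% of the CSS distribution (ties included).
Each scored SNP is assigned to every haplotype block containing it;
a block is *reported* iff it holds **more than 5** scored SNPs and at
least one outlier. Block membership uses one package-wide interval
rule — a position belongs to [start, end) iff start ≤ pos < end —
chosen so that abutting blocks never double-count a boundary SNP; the
same end-exclusive rule governs windows and simulated selected
regions.

## The synthetic-data generator

The generator emulates the sampling structure of a multi-stock
pool-seq experiment:

1. **Ancestral frequencies** per site from a Beta(0.5, 0.5) spectrum by
   default — U-shaped, concentrating mass near fixation as observed
   SNP panels do (configurable).
2. **Among-stock drift** via the Balding–Nichols model: each stock's
   frequency is Beta(p(1−F)/F, (1−p)(1−F)/F), with variance
   F·p(1−p). F defaults to 0.05 and may be given per stock; F = 0
   returns the ancestral frequency exactly, F ≥ 1 is rejected.
3. **Planted selection**: inside configured regions, affected stocks'
   frequencies are shifted by a constant (default studies use +0.4)
   and clipped to [0,1].
4. **Two-stage read sampling** per pool per site: a binomial draw of
   allele copies among the pool's 24 chromosomes (the pool-size
   variance floor that pool-seq estimators must tolerate — a direct
   binomial at the stock frequency would understate the variance),
   then Poisson depth (mean 30), then binomial read counts at the
   pool's realized frequency, then symmetric sequencing error: each
   read miscalls to one of the three other bases with probability
   0.001/3 each.

Defaults mirror the motivating experiment: 8 stocks, 12 pools per
stock, pools of 12 diploid workers (24 chromosomes), 30× mean depth.
Simulated haplotype blocks tile the genome with lengths uniform in
287–17,663 bp, the span of empirically derived honey bee haplotype
blocks. Per-base qualities are a non-issue by construction (counts are
emitted post-filtering, and the Q20 filter is recorded, not applied).

What the generator does **not** model — and hence what passing tests
do and do not show about real data: linkage and recombination (sites
are independent, so haplotype blocks carry no real LD signal),
within-stock pool relatedness (colonies sharing queens; pools are
exchangeable draws), indels and alignment artifacts, and depth
overdispersion beyond Poisson. Parameter-recovery results on this
generator demonstrate estimator correctness under the assumed sampling
model, not robustness to those real-data features.

Determinism: every generator seeds its own stream from the
configuration seed (with fixed per-stage offsets), so each stage is
individually reproducible and `emit_fixtures()` output is
byte-identical across runs.

## Numerical choices, in one place

* Oracle equivalence tolerance 1e-12 (vectorized vs naive per-site).
* k-means W floor 1e-12; restarts 25; `iter.max` 100.
* Quantile cuts via R's default (type 7) empirical quantile; "at or
  above the cut" with ties included.
* Ties: average ranks in fractional ranking; smallest k on elbow ties;
  A,T,C,G order breaks ties in major/minor allele identification.
* loess span 0.3, degree 1; constant profiles bypass the smoother.
* Mean imputation of missing pool frequencies before PCA (the simplest
  deterministic choice; missing entries are rare at 30× depth).
* Coordinates: sync and VCF positions are 1-based; BED intervals
  0-based half-open; the end-exclusive membership rule above is the
  only place the two meet, and it is property-tested at boundaries.

## Problem sizes used by the test suite

The suite exercises parameter recovery at sizes a desk machine handles
comfortably: the planted-selection study uses 50,000 sites × 96 pools
(10 selected regions covering 1% of sites, shift 0.4, drift F = 0.05,
depth 30); null calibration uses 10,000 SNPs × 4 contrasts; cluster
recovery uses 24 pools in 3 groups × 2,000 sites; oracle equivalence
uses 50–500-site fixtures. These sizes were chosen as the smallest at
which the Monte-Carlo tolerances quoted above are comfortably inside
sampling error.

## Known limitations

* Streaming: sync tables are loaded whole. At the scales this package
  targets (up to a few hundred thousand rows in memory at once) this
  is the idiomatic R trade-off; genome-scale runs should chunk by
  chromosome.
* π/θ are read-count estimators without Popoolation's truncated-count
  bias corrections; absolute levels are therefore comparable within
  this package, not with Popoolation output.
* The AIC formula assumes spherical shared-variance clusters; elongated
  clusters can shift the elbow.
* CSS assumes contrasts are independent under the null; contrasts
  sharing a reference population (as in resistant-vs-common-background
  designs) are positively correlated, which makes CSS p-values
  anti-conservative in absolute terms while leaving the outlier
  *ranking* meaningful.
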
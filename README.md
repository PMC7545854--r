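# poolscan

Population-genetic analysis of **pool-seq** data — whole-genome
sequencing of pooled individuals, which yields per-population allele
*frequencies* (read counts) rather than individual genotypes. The
package was built for multi-population panels such as managed honey
bee stocks, where each stock is sequenced as pools of workers and the
questions are: how diverse is each stock, how differentiated are they
from one another, how do they cluster, and which genomic regions carry
a shared signature of selection (for example, selection for
*Varroa*-resistance behavior)?

Input is the Popoolation2-style **sync** table (tab-separated
`chrom pos ref A:T:C:G:N:del …`, one count field per pool), plus a
pool panel (pool → stock mapping), optional BED haplotype blocks and
optional VCF allele frequencies. A built-in simulator generates sync
data with known truth so every stage can be validated end to end.

## What it computes

After conservative site filtering (minimum coverage 20, minimum
combined minor-allele count 10, per-pool 98th-percentile coverage
cap):

* **Diversity** — windowed nucleotide diversity
  π̂ = (C/(C−1))(1 − Σ f²) averaged over eligible sites, and
  Watterson's θ̂ = S/(a₍ₙ₋₁₎·L) with n the chromosomes in the pool;
  plus a 250-window smoothed locus profile (e.g. across the *csd*
  locus).
* **Differentiation** — per-SNP classical
  F_ST = (π_total − π_within)/π_total for every stock pair (including
  merged virtual stocks such as a generalized Italian background),
  genome-wide means, counts of fixed differentiation (F_ST > 0.65),
  top 1%/0.1% SNP sets, and stock-specific SNPs.
* **Structure** — PCA of pool allele frequencies (SNPs where some
  stock's minor-allele frequency exceeds 0.1), then k-means over
  k = 1–10 scored by AIC with elbow-based selection of k.
* **Selection** — the composite selection signal: per-contrast
  fractional ranks of F_ST → normal quantiles → per-SNP mean Z →
  one-sided p = 1 − Φ(z̄√m) → CSS = −log10(p); top-0.1% outliers are
  localized to haplotype blocks, reporting blocks with > 5 SNPs and
  ≥ 1 outlier.
* **Simulation** — Balding–Nichols among-stock drift
  (Var = F·p(1−p)), planted selected regions shared by a stock
  subset, and two-stage binomial read sampling (pool of 24
  chromosomes, then Poisson-depth reads at 30×, symmetric sequencing
  error).

See `vignettes/poolscan-methods.Rmd` for the full model description
and design rationale.

## Worked example

Simulate four stocks (two of them sharing a selected region), then run
differentiation, CSS and structure:

```r
library(poolscan)

cfg <- sim_config(n_stocks = 4, pools_per_stock = 3, n_sites = 20000,
                  drift_F = 0.05, seed = 42,
                  selected_regions = data.frame(
                    chrom = "LG1", start = 499999L, end = 520001L,
                    freq_shift = 0.4, stocks = "stock3,stock4"))
truth <- inject_selection(simulate_stock_frequencies(cfg), cfg)
sim   <- simulate_pool_reads(truth, cfg)
sim$sites
#> pool_sites: 20000 sites x 12 pools (LG1)

fst <- pairwise_scan(sim$sites, sim$panel)
round(genome_mean_fst(fst), 4)
#> stock1|stock2 stock1|stock3 stock1|stock4 stock2|stock3 stock2|stock4
#>        0.0317        0.0346        0.0337        0.0337        0.0331
#> stock3|stock4
#>        0.0323
```

The genome-wide means sit a little above the drift parameter
F = 0.05's expectation of a few percent because pool- and read-level
sampling add noise variance — the same upward pressure real pool-seq
F_ST estimates carry. Now combine the four contrasts of the selected
stocks against the unselected ones into a CSS scan:

```r
css <- css_score(fst[c("stock1|stock3", "stock1|stock4",
                       "stock2|stock3", "stock2|stock4")])
out <- top_css(css, q = 0.001)
head(out[order(-out$css), c("chrom", "pos", "z_mean", "p", "css")], 3)
#>      chrom    pos   z_mean            p      css
#> 2798   LG1 511000 3.127366 1.990988e-10 9.700931
#> 2786   LG1 509100 3.094335 3.033706e-10 9.518026
#> 2768   LG1 506200 2.974970 1.341208e-09 8.872504

eb <- map_to_blocks(out, css, simulate_blocks(cfg))
subset(eb, reported)[1:3, ]
#>    chrom  start    end    block_id snp_count outlier_count reported
#> 56   LG1 499905 506963 block_00056        48             6     TRUE
#> 57   LG1 508408 511881 block_00057        24             3     TRUE
#> 58   LG1 511905 522341 block_00058        57             2     TRUE
```

Every top CSS SNP and every reported block falls inside the planted
region [499999, 520001) — the scan localizes the shared signal. The
structure stage recovers the four stocks as four clusters of pools:

```r
res <- structure_scan(sim$sites, sim$panel, seed = 1)
res$k
#> [1] 4
table(sim$panel$stock, res$assignment)
#>          1 2 3 4
#>   stock1 0 0 3 0
#>   stock2 3 0 0 0
#>   stock3 0 0 0 3
#>   stock4 0 3 0 0
```

`run_pipeline()` chains all stages from one (YAML) configuration and
writes TSV outputs plus a manifest with parameters, seed and
checksums.

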
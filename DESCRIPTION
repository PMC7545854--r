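Package: poolscan
Title: Pool-Seq Population Genomics: Diversity, Differentiation and
    Composite Selection Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled whole-genome sequencing (pool-seq) allele
    count data for sets of populations such as managed honey bee stocks.
    Reads Popoolation2-style sync tables, applies conservative site
    filters, and estimates windowed nucleotide diversity (pi) and
    Watterson's theta, per-SNP pairwise FST with fixed-differentiation and
    stock-specific SNP extraction, population structure via PCA and
    k-means with AIC/elbow model selection, and a composite selection
    signal (CSS) scan with haplotype-block localization. Includes a
    two-stage binomial pool-seq simulator (Balding-Nichols among-stock
    drift, planted selected regions) so every stage is testable without
    raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
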
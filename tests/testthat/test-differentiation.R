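test_that("per-site FST hits its fixed points and the worked example", {
  # disjointly fixed pools
  expect_equal(site_fst(c(10, 0, 0, 0), c(0, 10, 0, 0)), 1)
  # identical count vectors: the C/(C-1) corrections of pi_within and
  # pi_total differ, leaving exactly -1/(2C-2) rather than 0
  expect_equal(site_fst(c(7, 3, 0, 0), c(7, 3, 0, 0)), -1 / 18)
  expect_lt(abs(site_fst(c(70, 30, 0, 0), c(70, 30, 0, 0))), 0.01)
  # (A:15,T:5) vs (A:5,T:15)
  pi_w <- (20 / 19) * (1 - (0.75^2 + 0.25^2))
  pi_t <- (40 / 39) * (1 - 0.5)
  expect_equal(site_fst(c(15, 5, 0, 0), c(5, 15, 0, 0)), (pi_t - pi_w) / pi_t)
  expect_equal(site_fst(c(15, 5, 0, 0), c(5, 15, 0, 0)), 0.230263,
               tolerance = 1e-6)
  # monomorphic combined site is undefined
  expect_true(is.na(site_fst(c(10, 0, 0, 0), c(5, 0, 0, 0))))
})

test_that("FST is symmetric, relabeling-invariant, and matches the oracle", {
  x <- random_fixture(100, 2, seed = 21)
  ca <- t(vapply(seq_len(100), function(i) x$counts[i, 1:4, 1], numeric(4)))
  cb <- t(vapply(seq_len(100), function(i) x$counts[i, 1:4, 2], numeric(4)))
  f1 <- site_fst(ca, cb)
  expect_equal(f1, site_fst(cb, ca))
  relabel <- c(4, 3, 2, 1)
  expect_equal(site_fst(ca[, relabel], cb[, relabel]), f1)
  want <- vapply(seq_len(100), function(i) oracle_site_fst(ca[i, ], cb[i, ]),
                 numeric(1))
  expect_equal(f1, want, tolerance = 1e-12)
  # fixed points across random coverages
  withr::with_seed(2, {
    for (rep in 1:20) {
      d1 <- sample(5:60, 1); d2 <- sample(5:60, 1)
      same <- c(d1, d2, 0, 0)
      expect_equal(site_fst(same, same), -1 / (2 * (d1 + d2) - 2))
      expect_equal(site_fst(c(d1, 0, 0, 0), c(0, d2, 0, 0)), 1)
    }
  })
})

test_that("pairwise scan restricts to pair SNPs and reports means", {
  cfg <- sim_config(n_stocks = 3, pools_per_stock = 2, n_sites = 3000,
                    drift_F = 0, seq_error = 0, seed = 31)
  sim <- simulate_pool_reads(simulate_stock_frequencies(cfg), cfg)
  tabs <- pairwise_scan(sim$sites, sim$panel)
  expect_named(tabs, c("stock1|stock2", "stock1|stock3", "stock2|stock3"))
  # null case: zero drift -> genome mean dominated by sampling noise only,
  # and equal across pairs
  means <- genome_mean_fst(tabs)
  expect_lt(max(means), 0.06)
  expect_lt(max(means) - min(means), 0.01)
  # table rows are exactly the SNPs classified for the pair
  tr <- poolscan:::stock_tracks(sim$sites, sim$panel)
  caps <- max_coverage_caps(tr$sites, filter_config())
  cl <- classify_sites(tr$sites, filter_config(),
                       pools = c("stock1", "stock2"), caps = caps)
  expect_equal(nrow(tabs[["stock1|stock2"]]), sum(cl$sites$snp))
})

test_that("higher-drift stock pairs show higher genome-wide FST", {
  cfg <- sim_config(n_stocks = 4, pools_per_stock = 2, n_sites = 4000,
                    drift_F = c(0.01, 0.01, 0.15, 0.15), seed = 33)
  sim <- simulate_pool_reads(simulate_stock_frequencies(cfg), cfg)
  tabs <- pairwise_scan(sim$sites, sim$panel,
                        pairs = list(c("stock1", "stock2"),
                                     c("stock3", "stock4")))
  means <- genome_mean_fst(tabs)
  expect_gt(means[["stock3|stock4"]], means[["stock1|stock2"]])
})

test_that("fixed differentiation counts strict exceedances", {
  tbl <- data.frame(chrom = "chr1", pos = 1:3, fst = c(0.7, 0.6, 0.66))
  expect_equal(fixed_differentiation(tbl, 0.65)$count, 2)
  expect_equal(fixed_differentiation(tbl, 1.0)$count, 0)
  # planted fixed differences (freq 0 vs 1, no error) are all recovered
  cfg <- sim_config(n_stocks = 2, pools_per_stock = 2, n_sites = 500,
                    drift_F = 0, seq_error = 0, seed = 35)
  truth <- simulate_stock_frequencies(cfg)
  fixed_idx <- seq(10, 400, by = 10)
  truth$stock1[fixed_idx] <- 0
  truth$stock2[fixed_idx] <- 1
  sim <- simulate_pool_reads(truth, cfg)
  tab <- pairwise_scan(sim$sites, sim$panel)[[1]]
  fd <- fixed_differentiation(tab, 0.65)
  planted <- truth$pos[fixed_idx]
  found <- fd$snps$pos
  snp_positions <- tab$pos
  expect_true(all(intersect(planted, snp_positions) %in% found))
  expect_true(all(tab$fst[tab$pos %in% planted] == 1))
})

test_that("top-quantile extraction keeps ties at the cut", {
  tbl <- data.frame(chrom = "chr1", pos = 1:1000,
                    fst = withr::with_seed(4, sample(seq(0.001, 1, length.out = 1000))))
  top <- top_quantile(tbl, 0.001)
  expect_equal(nrow(top), 1L)
  expect_equal(top$fst, max(tbl$fst))
  expect_equal(nrow(top_quantile(tbl, 1.0)), 1000L)
  tied <- data.frame(chrom = "chr1", pos = 1:50, fst = 0.5)
  expect_equal(nrow(top_quantile(tied, 0.01)), 50L)
})

test_that("stock-specific SNPs follow the every-comparison-then-unique rule", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos, fst = 0.9)
  # SNP 1 is top-q in both comparisons involving A and nowhere else
  tops <- list("A|B" = mk(c(1, 2)), "A|C" = mk(c(1, 3)), "B|C" = mk(c(4)))
  sp <- stock_specific_snps(tops, c("A", "B", "C"))
  expect_equal(sp$A$pos, 1L)
  expect_equal(nrow(sp$B), 0L)
  expect_equal(nrow(sp$C), 0L)
  # a SNP in only one of a stock's comparisons is candidate for neither side
  tops2 <- list("A|B" = mk(9), "A|C" = mk(3), "B|C" = mk(4))
  sp2 <- stock_specific_snps(tops2, c("A", "B", "C"))
  expect_equal(vapply(sp2, nrow, integer(1)), c(A = 0L, B = 0L, C = 0L))
  # a SNP shared by two stocks' full comparison sets is specific to neither
  tops3 <- list("A|B" = mk(c(1, 7)), "A|C" = mk(c(1, 7)), "B|C" = mk(c(7)))
  sp3 <- stock_specific_snps(tops3, c("A", "B", "C"))
  expect_equal(sp3$A$pos, 1L)    # 1 is candidate only for A
  expect_equal(nrow(sp3$B), 0L)  # 7 is candidate for both A and B
  # the union rule makes every pair SNP a candidate for both its stocks,
  # so none of these singleton-pair SNPs can be unique to one stock
  sp_any <- stock_specific_snps(tops2, c("A", "B", "C"), rule = "any")
  expect_equal(vapply(sp_any, nrow, integer(1)), c(A = 0L, B = 0L, C = 0L))
  # missing pair is reported by name
  expect_error(stock_specific_snps(tops[1:2], c("A", "B", "C")), "B|C")
})

test_that("scan equals per-site FST applied independently", {
  x <- random_fixture(200, 4, seed = 41)
  panel <- pool_panel(x$pools, c("s1", "s1", "s2", "s2"))
  filters <- filter_config(min_coverage = 30, min_count = 5)
  tabs <- pairwise_scan(x, panel, filters = filters)
  tr <- poolscan:::stock_tracks(x, panel)
  caps <- max_coverage_caps(tr$sites, filters)
  cl <- classify_sites(tr$sites, filters, caps = caps)
  idx <- which(cl$sites$snp)
  want <- vapply(idx, function(i) {
    oracle_site_fst(tr$sites$counts[i, 1:4, "s1"], tr$sites$counts[i, 1:4, "s2"])
  }, numeric(1))
  expect_equal(tabs[["s1|s2"]]$fst, want[!is.na(want)], tolerance = 1e-12)
})
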
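test_that("fractional ranks map into the open unit interval", {
  expect_equal(fractional_ranks(c(0.1, 0.4, 0.2, 0.3)), c(0.2, 0.8, 0.4, 0.6))
  expect_equal(fractional_ranks(rep(1.5, 3)), rep(0.5, 3))  # average ties
  r <- fractional_ranks(1:100)
  expect_equal(max(r), 100 / 101)
  expect_true(all(r > 0 & r < 1))
  expect_error(fractional_ranks(c(1, NA)), "finite")
})

test_that("rank-to-Z is the standard normal quantile", {
  expect_equal(rank_to_z(0.5), 0)
  expect_equal(rank_to_z(0.8), 0.841621, tolerance = 1e-6)
  r <- c(0.1, 0.25, 0.4)
  expect_equal(rank_to_z(r), -rank_to_z(1 - r))
  expect_error(rank_to_z(1), "strictly")
  expect_error(rank_to_z(0), "strictly")
})

test_that("CSS combines mean Z against its exact null", {
  # m = 1, median SNP: p = 0.5, CSS = -log10(0.5)
  one <- list(a = data.frame(chrom = "c", pos = 1, fst = 0.2))
  res1 <- css_score(one)
  expect_equal(res1$p, 0.5)
  expect_equal(res1$css, 0.301030, tolerance = 1e-6)
  # m = 4, zbar = 1: p = 1 - Phi(2)
  expect_equal(1 - pnorm(2), 0.022750, tolerance = 1e-4)
  expect_equal(-log10(1 - pnorm(2)), 1.6430, tolerance = 1e-4)
  # engineered table where one SNP attains zbar ~ known value
  n <- 399
  mk <- function(seed) data.frame(chrom = "c", pos = 1:n,
                                  fst = withr::with_seed(seed, runif(n)))
  tabs <- lapply(1:4, mk)
  # plant the same top SNP in all four comparisons
  for (j in 1:4) tabs[[j]]$fst[7] <- 2
  res <- css_score(tabs)
  z_top <- qnorm(n / (n + 1))
  i <- which(res$pos == 7)
  expect_equal(res$z_mean[i], z_top)
  expect_equal(res$p[i], pnorm(z_top * 2, lower.tail = FALSE))
  expect_equal(res$css[i], -log10(res$p[i]))
})

test_that("CSS is invariant under monotone transforms of each comparison", {
  n <- 200
  tabs <- lapply(1:3, function(j) {
    data.frame(chrom = "c", pos = 1:n,
               fst = withr::with_seed(50 + j, runif(n)))
  })
  res <- css_score(tabs)
  warped <- lapply(tabs, function(t) {
    t$fst <- exp(5 * t$fst) - 0.2   # strictly increasing transform
    t
  })
  expect_equal(css_score(warped)$css, res$css, tolerance = 1e-12)
})

test_that("complete-case policy drops SNPs absent from any comparison", {
  t1 <- data.frame(chrom = "c", pos = 1:10, fst = (1:10) / 20)
  t2 <- data.frame(chrom = "c", pos = 3:12, fst = (1:10) / 15)
  res <- css_score(list(a = t1, b = t2))
  expect_equal(res$pos, 3:10)
  expect_true(all(res$m == 2))
  avail <- css_score(list(a = t1, b = t2), policy = "available")
  expect_equal(avail$pos, 1:12)
  expect_equal(avail$m[avail$pos == 1], 1)
})

test_that("CSS matches a naive sort-based oracle to 1e-9", {
  n <- 100
  tabs <- lapply(1:4, function(j) {
    data.frame(chrom = "c", pos = 1:n,
               fst = withr::with_seed(60 + j, runif(n)))
  })
  got <- css_score(tabs)
  want <- oracle_css(tabs)
  want <- want[match(paste("c", got$pos, sep = ":"), want$key), ]
  expect_equal(got$z_mean, want$z_mean, tolerance = 1e-9)
  expect_equal(got$css, want$css, tolerance = 1e-9)
})

test_that("null CSS p-values are uniform", {
  n <- 10000
  tabs <- lapply(1:4, function(j) {
    data.frame(chrom = "c", pos = 1:n,
               fst = withr::with_seed(70 + j, rexp(n)))
  })
  res <- css_score(tabs)
  expect_equal(mean(res$p < 0.05), 0.05, tolerance = 0.2)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("top CSS outliers dominate every non-outlier", {
  n <- 1000
  res <- data.frame(chrom = "c", pos = 1:n,
                    css = withr::with_seed(80, sample(seq_len(n) / 10)))
  class(res) <- c("css_result", "data.frame")
  top <- top_css(res, 0.001)
  expect_equal(nrow(top), 1L)
  expect_equal(top$css, max(res$css))
  half <- top_css(res, 0.5)
  expect_gte(min(half$css), max(res$css[!res$pos %in% half$pos]))
})

test_that("block localization applies the >5 SNP rule and end exclusion", {
  blocks <- data.frame(chrom = "LG1", start = 100L, end = 200L,
                       block_id = "b1")
  snps <- data.frame(chrom = "LG1", pos = 101:106,
                     css = c(9, 1, 1, 1, 1, 1))
  out <- snps[1, , drop = FALSE]
  eb <- map_to_blocks(out, snps, blocks)
  expect_equal(eb$snp_count, 6L)
  expect_true(eb$reported)          # 6 > 5 with one outlier
  # exactly 5 SNPs: not reported (strict inequality)
  eb5 <- map_to_blocks(out, snps[1:5, ], blocks)
  expect_false(eb5$reported)
  # a SNP at the block end is outside the half-open interval
  at_end <- data.frame(chrom = "LG1", pos = 200L, css = 9)
  expect_equal(map_to_blocks(at_end, at_end, blocks)$snp_count, 0L)
  at_start <- data.frame(chrom = "LG1", pos = 100L, css = 9)
  expect_equal(map_to_blocks(at_start, at_start, blocks)$snp_count, 1L)
  # no outlier inside: block counted but not reported
  eb0 <- map_to_blocks(snps[0, ], snps, blocks)
  expect_false(eb0$reported)
  expect_equal(eb0$snp_count, 6L)
})
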
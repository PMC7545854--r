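test_that("Balding-Nichols drift has the right limits and variance", {
  # zero drift: stock frequencies equal the ancestral exactly
  cfg0 <- sim_config(n_stocks = 3, pools_per_stock = 1, n_sites = 200,
                     drift_F = 0, seed = 1)
  t0 <- simulate_stock_frequencies(cfg0)
  expect_equal(t0$stock1, t0$p_ancestral)
  expect_equal(t0$stock3, t0$p_ancestral)
  # F >= 1 rejected
  expect_error(sim_config(drift_F = 1), "drift_F")
  # moment check: with p ~= 0.5 and F = 0.05, Var(q) ~= F p (1-p) = 0.0125
  cfg <- sim_config(n_stocks = 2, pools_per_stock = 1, n_sites = 10000,
                    drift_F = 0.05, ancestral_shape = c(5e5, 5e5), seed = 2)
  tt <- simulate_stock_frequencies(cfg)
  expect_equal(var(tt$stock1), 0.0125, tolerance = 0.1)
  expect_equal(var(tt$stock2), 0.0125, tolerance = 0.1)
  # determinism: identical truth under identical seed
  expect_identical(simulate_stock_frequencies(cfg), tt)
})

test_that("selection injection shifts, clips and flags only its targets", {
  reg <- data.frame(chrom = "LG1", start = 0L, end = 5001L,
                    freq_shift = 0.3, stocks = "stock1")
  cfg <- sim_config(n_stocks = 2, pools_per_stock = 1, n_sites = 100,
                    selected_regions = reg, seed = 3)
  truth <- simulate_stock_frequencies(cfg)
  truth$stock1 <- 0.9   # force a clip
  shifted <- inject_selection(truth, cfg)
  hit <- truth$pos >= 0 & truth$pos < 5001
  expect_true(all(shifted$stock1[hit] == 1.0))        # 0.9 + 0.3 clipped
  expect_equal(shifted$stock1[!hit], truth$stock1[!hit])
  expect_equal(shifted$stock2, truth$stock2)          # unaffected stock
  expect_equal(shifted$selected, hit)
  # zero shift is the identity
  cfg0 <- sim_config(n_stocks = 2, pools_per_stock = 1, n_sites = 100,
                     selected_regions = transform(reg, freq_shift = 0),
                     seed = 3)
  same <- inject_selection(truth, cfg0)
  expect_equal(same$stock1, truth$stock1)
  # region beyond the simulated coordinates is an error
  far <- transform(reg, start = 1e7, end = 2e7)
  cfg_far <- sim_config(n_stocks = 2, pools_per_stock = 1, n_sites = 100,
                        selected_regions = far, seed = 3)
  expect_error(inject_selection(truth, cfg_far), "outside")
  # overlapping regions rejected at configuration
  reg2 <- rbind(reg, transform(reg, start = 4000L, end = 9000L))
  expect_error(sim_config(n_stocks = 2, selected_regions = reg2), "overlap")
})

test_that("selection raises truth-level FST inside regions", {
  cfg <- sim_config(n_stocks = 8, pools_per_stock = 1, n_sites = 5000,
                    drift_F = 0.05, seed = 5)
  regions <- place_selected_regions(cfg, paste0("stock", 1:4), 0.4,
                                    fraction = 0.05, n_regions = 5)
  cfg <- sim_config(n_stocks = 8, pools_per_stock = 1, n_sites = 5000,
                    drift_F = 0.05, selected_regions = regions, seed = 5)
  truth <- inject_selection(simulate_stock_frequencies(cfg), cfg)
  # FST between an affected stock and the merged unaffected background
  bg <- rowMeans(as.matrix(truth[paste0("stock", 5:8)]))
  fst <- oracle_fst_from_freqs(truth$stock1, bg)
  inside <- median(fst[truth$selected], na.rm = TRUE)
  genome_median <- median(fst, na.rm = TRUE)
  expect_gt(inside, genome_median)
})

test_that("pool read simulation has the stated sampling moments", {
  # seq_error = 0, true frequency 0: every read carries the reference base
  cfg <- sim_config(n_stocks = 1, pools_per_stock = 2, n_sites = 300,
                    seq_error = 0, seed = 6)
  truth <- simulate_stock_frequencies(cfg)
  truth$stock1 <- 0
  sim <- simulate_pool_reads(truth, cfg)
  ref_counts <- vapply(seq_len(300), function(i) {
    sum(sim$sites$counts[i, sim$sites$ref[i], ])
  }, numeric(1))
  expect_equal(unname(ref_counts), unname(rowSums(pool_coverage(sim$sites))))
  # realized mean coverage within 2% of depth_mean over 10,000 sites
  cfg2 <- sim_config(n_stocks = 1, pools_per_stock = 1, n_sites = 10000,
                     depth_mean = 30, seed = 7)
  sim2 <- simulate_pool_reads(simulate_stock_frequencies(cfg2), cfg2)
  expect_equal(mean(pool_coverage(sim2$sites)), 30, tolerance = 0.02)
  # read-frequency estimator unbiased at true frequency 0.5
  cfg3 <- sim_config(n_stocks = 1, pools_per_stock = 1, n_sites = 10000,
                     depth_mean = 100, seq_error = 0, seed = 8)
  truth3 <- simulate_stock_frequencies(cfg3)
  truth3$stock1 <- 0.5
  sim3 <- simulate_pool_reads(truth3, cfg3)
  alt <- vapply(seq_len(10000), function(i) {
    cov_i <- sum(sim3$sites$counts[i, 1:4, 1])
    (cov_i - sim3$sites$counts[i, sim3$sites$ref[i], 1]) / cov_i
  }, numeric(1))
  expect_equal(mean(alt, na.rm = TRUE), 0.5, tolerance = 0.02)
})

test_that("equal drift without selection gives exchangeable pairwise FST", {
  cfg <- sim_config(n_stocks = 4, pools_per_stock = 2, n_sites = 5000,
                    drift_F = 0.05, seed = 9)
  sim <- simulate_pool_reads(simulate_stock_frequencies(cfg), cfg)
  means <- genome_mean_fst(pairwise_scan(sim$sites, sim$panel))
  expect_lt((max(means) - min(means)) / mean(means), 0.15)
})

test_that("fixture emission writes four deterministic files", {
  cfg <- sim_config(n_stocks = 2, pools_per_stock = 1, n_sites = 100,
                    seed = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths <- emit_fixtures(cfg, d1)
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  c("counts.sync", "blocks.bed", "truth.tsv", "config.yml"))
  paths2 <- emit_fixtures(cfg, d2)
  expect_identical(unname(tools::md5sum(paths)), unname(tools::md5sum(paths2)))
  # the sync file reloads against the implied panel
  x <- read_sync(paths[["sync"]], panel_from_config(cfg))
  expect_equal(n_sites(x), 100L)
  # block lengths stay inside the empirical haplotype-block range
  big <- sim_config(n_stocks = 2, pools_per_stock = 1, n_sites = 3000,
                    seed = 10)
  blocks <- simulate_blocks(big)
  expect_gt(nrow(blocks), 5L)
  len <- blocks$end - blocks$start
  expect_true(all(len >= 287 & len <= 17663))
})
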
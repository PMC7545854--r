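# build a pool_sites object from per-pool count matrices (n x 4 in
# A,T,C,G order, or n x 6 with N/del columns)
make_sites <- function(..., chrom = "chr1", pos = NULL, ref = "A",
                       pools = NULL) {
  mats <- lapply(list(...), function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (ncol(m) == 4) m <- cbind(m, 0L, 0L)
    m
  })
  n <- nrow(mats[[1]])
  if (is.null(pos)) pos <- seq_len(n)
  if (is.null(pools)) pools <- paste0("pool", seq_along(mats))
  counts <- array(0L, c(n, 6, length(mats)))
  for (j in seq_along(mats)) counts[, , j] <- as.integer(mats[[j]])
  pool_sites(rep_len(chrom, n), pos, rep_len(ref, n), counts, pools = pools)
}

# permissive filters for fixtures built without realistic coverages
open_filters <- function(min_coverage = 1, min_count = 1) {
  filter_config(min_coverage = min_coverage, min_count = min_count,
                max_cov_percentile = 100)
}

# random multi-pool count fixture: biallelic sites with random depths
random_fixture <- function(n_sites, n_pools, seed, depth = 30) {
  withr::with_seed(seed, {
    counts <- array(0L, c(n_sites, 6, n_pools))
    ref_i <- sample.int(4, n_sites, replace = TRUE)
    alt_i <- vapply(ref_i, function(r) sample(setdiff(1:4, r), 1L), integer(1))
    f <- stats::runif(n_sites)
    for (j in seq_len(n_pools)) {
      d <- stats::rpois(n_sites, depth)
      a <- stats::rbinom(n_sites, d, f)
      counts[cbind(seq_len(n_sites), ref_i, j)] <- d - a
      counts[cbind(seq_len(n_sites), alt_i, j)] <- a
    }
    pool_sites(rep("chr1", n_sites), seq_len(n_sites) * 10L,
               c("A", "T", "C", "G")[ref_i], counts,
               pools = paste0("pool", seq_len(n_pools)))
  })
}
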
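# Independent naive (per-site, loop-based) oracle implementations used to
# verify the vectorized estimators. They are deliberately written from the
# formulas, not by calling package internals.

oracle_site_pi <- function(counts4) {
  C <- sum(counts4)
  if (C < 2) return(NA_real_)
  f <- counts4 / C
  C / (C - 1) * (1 - sum(f^2))
}

oracle_site_fst <- function(counts_a, counts_b) {
  pi_a <- oracle_site_pi(counts_a)
  pi_b <- oracle_site_pi(counts_b)
  pi_t <- oracle_site_pi(counts_a + counts_b)
  if (is.na(pi_t) || pi_t == 0) return(NA_real_)
  (pi_t - (pi_a + pi_b) / 2) / pi_t
}

# expected FST implied by two population allele frequencies (infinite
# sample size, no C/(C-1) correction): used on simulator truth tables
oracle_fst_from_freqs <- function(fa, fb) {
  pi_a <- 2 * fa * (1 - fa)
  pi_b <- 2 * fb * (1 - fb)
  fm <- (fa + fb) / 2
  pi_t <- 2 * fm * (1 - fm)
  ifelse(pi_t > 0, (pi_t - (pi_a + pi_b) / 2) / pi_t, NA_real_)
}

# two-pass per-site windowed pi/theta: loops over windows and sites
oracle_window_stats <- function(x, windows, filters, pools, n_chrom) {
  caps <- poolscan::max_coverage_caps(
    poolscan::subset_sites(x, pools = pools), filters)
  cov <- poolscan::pool_coverage(x)[, pools, drop = FALSE]
  a <- sum(1 / seq_len(n_chrom - 1))
  res <- data.frame(pi = numeric(nrow(windows)), theta = numeric(nrow(windows)),
                    n_eligible = integer(nrow(windows)),
                    n_snps = integer(nrow(windows)))
  for (w in seq_len(nrow(windows))) {
    pis <- c(); S <- 0L; nel <- 0L
    for (i in seq_along(x$pos)) {
      if (x$chrom[i] != windows$chrom[w]) next
      if (!(x$pos[i] >= windows$start[w] && x$pos[i] < windows$end[w])) next
      cvi <- cov[i, ]
      if (any(cvi < filters$min_coverage) || any(cvi > caps[pools])) next
      comb <- rowSums(vapply(pools, function(p) x$counts[i, 1:4, p],
                             numeric(4)))
      pi_i <- oracle_site_pi(comb)
      if (is.na(pi_i)) next
      nel <- nel + 1L
      pis <- c(pis, pi_i)
      minor <- sort(comb, decreasing = TRUE)[2]
      if (minor >= filters$min_count) S <- S + 1L
    }
    res$n_eligible[w] <- nel
    res$n_snps[w] <- S
    res$pi[w] <- if (nel > 0) sum(pis) / nel else NA_real_
    res$theta[w] <- if (nel > 0) S / (a * nel) else NA_real_
  }
  res
}

# naive CSS: sort-based fractional ranks, per-SNP mean Z, upper-tail p
oracle_css <- function(fst_tables) {
  keys_list <- lapply(fst_tables, function(t) paste(t$chrom, t$pos, sep = ":"))
  zs <- lapply(fst_tables, function(t) {
    v <- t$fst
    N <- length(v)
    r <- vapply(seq_len(N), function(i) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      (less + (ties + 1) / 2) / (N + 1)
    }, numeric(1))
    stats::qnorm(r)
  })
  common <- Reduce(intersect, keys_list)
  zmat <- vapply(seq_along(zs), function(j) {
    zs[[j]][match(common, keys_list[[j]])]
  }, numeric(length(common)))
  zmat <- matrix(zmat, nrow = length(common))
  m <- ncol(zmat)
  zbar <- rowMeans(zmat)
  p <- 1 - stats::pnorm(zbar * sqrt(m))
  data.frame(key = common, z_mean = zbar, p = p, css = -log10(p),
             stringsAsFactors = FALSE)
}

# neutral-equilibrium sampler for a pool of n chromosomes: each site
# segregates with probability theta0 * a_{n-1}; conditional on
# segregating, the derived-allele copy count i follows the neutral SFS,
# P(i) proportional to 1/i over i = 1..n-1 (under which E[pi] =
# E[theta] = theta0). Reads mirror chromosomes 1:1 so the read-level
# estimators see the sample frequencies exactly.
neutral_sfs_sites <- function(n_sites, n_chrom, theta0, seed) {
  withr::with_seed(seed, {
    a <- sum(1 / seq_len(n_chrom - 1))
    seg <- stats::runif(n_sites) < theta0 * a
    i <- integer(n_sites)
    w <- 1 / seq_len(n_chrom - 1)
    i[seg] <- sample(seq_len(n_chrom - 1), sum(seg), replace = TRUE,
                     prob = w / sum(w))
  })
  counts <- matrix(0L, n_sites, 4)
  counts[, 1] <- as.integer(n_chrom - i)
  counts[, 2] <- as.integer(i)
  make_sites(counts, pos = seq_len(n_sites) * 10L)
}
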
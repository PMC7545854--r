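#' Site filter settings
#'
#' The conservative SNP filters applied before any estimator: a minimum
#' per-pool coverage, a minimum combined minor-allele count, a minimum
#' base quality (recorded only — sync counts carry no per-base qualities,
#' so Q filtering is assumed to have happened upstream), and a per-pool
#' maximum-coverage cap expressed as a coverage-distribution percentile
#' that guards against collapsed repeats and CNVs.
#'
#' @param min_coverage Minimum reads per in-scope pool (default 20).
#' @param min_count Minimum combined minor-allele read count (default 10).
#' @param min_quality Phred threshold, recorded for provenance (default 20).
#' @param max_cov_percentile Percentile (in (0,100]) of each pool's coverage
#'   distribution used as its coverage cap; default 98, i.e. the top 2%
#'   highest-coverage sites are excluded.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 20, min_count = 10,
                          min_quality = 20, max_cov_percentile = 98) {
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  if (min_count < 1) stop("min_count must be >= 1")
  if (max_cov_percentile <= 0 || max_cov_percentile > 100) {
    stop("max_cov_percentile must be in (0, 100]")
  }
  structure(list(min_coverage = min_coverage, min_count = min_count,
                 min_quality = min_quality,
                 max_cov_percentile = max_cov_percentile),
            class = "filter_config")
}

#' Per-pool maximum-coverage caps
#'
#' The cap for each pool is the configured percentile of that pool's
#' empirical coverage distribution. With fewer than 100 sites the
#' percentile is too unstable to estimate and the cap is `Inf` (with a
#' warning), excluding nothing.
#'
#' @param x A `pool_sites` object.
#' @param filters A [filter_config()].
#' @return Named numeric vector of caps, one per pool.
#' @export
max_coverage_caps <- function(x, filters = filter_config()) {
  cov <- pool_coverage(x)
  if (nrow(cov) < 100L) {
    warning("fewer than 100 sites: max-coverage caps set to Inf")
    return(stats::setNames(rep(Inf, ncol(cov)), colnames(cov)))
  }
  caps <- apply(cov, 2, stats::quantile,
                probs = filters$max_cov_percentile / 100, names = FALSE)
  stats::setNames(as.numeric(caps), colnames(cov))
}

# counts: numeric matrix n x 4 in A,T,C,G order (summed over a pool scope)
# returns per-site pi-hat = (C/(C-1)) * (1 - sum f^2); NA where C < 2
site_pi_counts <- function(counts) {
  C <- rowSums(counts)
  f2 <- rowSums((counts / ifelse(C > 0, C, 1))^2)
  ifelse(C >= 2, C / (C - 1) * (1 - f2), NA_real_)
}

#' Per-site heterozygosity (pi-hat)
#'
#' The site-level nucleotide diversity estimate over the four bases,
#' with the small-sample correction C/(C-1) on the read count C:
#' pi-hat = (C/(C-1)) (1 - sum_a f_a^2). Counts are summed across the
#' given pools before the frequencies are formed. Monomorphic sites give
#' exactly 0; sites with combined coverage below 2 are undefined (`NA`).
#'
#' @param x A `pool_sites` object.
#' @param pools Pools whose counts are summed (default: all).
#' @return Numeric vector of per-site pi-hat.
#' @export
site_heterozygosity <- function(x, pools = NULL) {
  if (is.null(pools)) pools <- x$pools
  cc <- combined_base_counts(x, pools)
  site_pi_counts(cc)
}

# n x 4 matrix of base counts summed over pools, A,T,C,G order
combined_base_counts <- function(x, pools) {
  cc <- x$counts[, SYNC_BASES, pools, drop = FALSE]
  out <- rowSums(cc, dims = 2)  # sum over the pool dimension
  dim(out) <- c(length(x$pos), 4L)
  colnames(out) <- SYNC_BASES
  out
}

#' Classify sites: eligibility and SNP status
#'
#' A site is *eligible* iff every in-scope pool's coverage lies within
#' `[min_coverage, cap]` (caps per [max_coverage_caps()]). An eligible
#' site is a *SNP* iff the combined (summed over in-scope pools)
#' minor-allele count reaches `min_count`. Major and minor alleles are
#' the two most frequent bases of the combined counts.
#'
#' @param x A `pool_sites` object.
#' @param filters A [filter_config()].
#' @param pools Scope: pool labels to consider (default: all pools).
#' @param caps Optional precomputed caps (named as pools); computed from
#'   the in-scope pools of `x` when `NULL`.
#' @return A list of class `site_class`: `sites` (`data.frame` with
#'   `chrom`, `pos`, `eligible`, `snp`, `major`, `minor`, `minor_count`),
#'   `freq` (matrix of per-pool minor-allele frequencies, `NA` where a
#'   pool has zero coverage), plus the scope and caps used.
#' @export
classify_sites <- function(x, filters = filter_config(), pools = NULL,
                           caps = NULL) {
  if (is.null(pools)) pools <- x$pools
  if (length(pools) == 0L) stop("pool scope must be non-empty")
  if (is.null(caps)) {
    caps <- max_coverage_caps(subset_sites(x, pools = pools), filters)
  }
  caps <- caps[pools]
  cov <- pool_coverage(x)[, pools, drop = FALSE]
  ok <- cov >= filters$min_coverage &
    cov <= matrix(caps, nrow(cov), length(pools), byrow = TRUE)
  eligible <- rowSums(ok) == length(pools)

  comb <- combined_base_counts(x, pools)
  n <- length(x$pos)
  # major = most frequent base, minor = second; ties resolved in A,T,C,G order
  major_i <- max.col(comb, ties.method = "first")
  tmp <- comb
  tmp[cbind(seq_len(n), major_i)] <- -1L
  minor_i <- max.col(tmp, ties.method = "first")
  minor_count <- comb[cbind(seq_len(n), minor_i)]
  snp <- eligible & minor_count >= filters$min_count

  minor_base <- SYNC_BASES[minor_i]
  freq <- vapply(pools, function(p) {
    cnt <- x$counts[, SYNC_BASES, p, drop = FALSE]
    dim(cnt) <- c(n, 4L)
    mc <- cnt[cbind(seq_len(n), minor_i)]
    cv <- cov[, p]
    ifelse(cv > 0, mc / cv, NA_real_)
  }, numeric(n))
  dim(freq) <- c(n, length(pools))
  colnames(freq) <- pools

  structure(list(
    sites = data.frame(chrom = x$chrom, pos = x$pos, eligible = eligible,
                       snp = snp, major = SYNC_BASES[major_i],
                       minor = minor_base, minor_count = minor_count,
                       stringsAsFactors = FALSE),
    freq = freq, pools = pools, caps = caps, filters = filters
  ), class = "site_class")
}

#' Merge pools into one virtual pool
#'
#' Sums per-site counts element-wise across a pool subset, e.g. to form
#' the generalized Italian background from the commercial Italian-derived
#' stocks. Count conservation is exact.
#'
#' @param x A `pool_sites` object.
#' @param pools Non-empty character vector of pool labels to merge.
#' @param label Label for the resulting virtual pool.
#' @return A `pool_sites` object with a single pool.
#' @export
merge_pools <- function(x, pools, label = "merged") {
  if (length(pools) == 0L) stop("cannot merge an empty pool subset")
  missing_p <- setdiff(pools, x$pools)
  if (length(missing_p)) stop("unknown pools: ", paste(missing_p, collapse = ", "))
  cc <- x$counts[, , pools, drop = FALSE]
  summed <- rowSums(cc, dims = 2)  # sum over the pool dimension
  dim(summed) <- c(length(x$pos), 6L)
  counts <- array(summed, c(length(x$pos), 6L, 1L))
  pool_sites(x$chrom, x$pos, x$ref, counts, pools = label)
}

# one virtual pool per stock (counts summed across its pools); optionally
# adds merged virtual stocks, e.g. merge = list(Italian = c("It1","It2","It3"))
stock_tracks <- function(x, panel, merge = NULL) {
  stocks <- unique(panel$stock)
  tracks <- lapply(stocks, function(s) {
    merge_pools(x, panel$pool[panel$stock == s], label = s)
  })
  names(tracks) <- stocks
  chroms <- vapply(stocks, function(s) sum(panel$n_chromosomes[panel$stock == s]),
                   numeric(1))
  if (!is.null(merge)) {
    for (lab in names(merge)) {
      members <- merge[[lab]]
      missing_s <- setdiff(members, stocks)
      if (length(missing_s)) {
        stop("merge refers to unknown stocks: ", paste(missing_s, collapse = ", "))
      }
      tracks[[lab]] <- merge_pools(x, panel$pool[panel$stock %in% members],
                                   label = lab)
      chroms[lab] <- sum(chroms[members])
    }
  }
  n <- length(x$pos)
  counts <- array(0L, c(n, 6L, length(tracks)),
                  dimnames = list(NULL, SYNC_COLS, names(tracks)))
  for (j in seq_along(tracks)) counts[, , j] <- tracks[[j]]$counts[, , 1]
  list(sites = pool_sites(x$chrom, x$pos, x$ref, counts, pools = names(tracks)),
       n_chromosomes = chroms)
}
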
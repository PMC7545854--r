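#' Harmonic number used by Watterson's estimator
#'
#' `watterson_a(n)` returns a_{n-1} = sum_{i=1}^{n-1} 1/i for a sample of
#' `n` chromosomes.
#'
#' @param n Number of sampled chromosomes (>= 2).
#' @return The harmonic sum a_{n-1}.
#' @export
watterson_a <- function(n) {
  if (n < 2) stop("Watterson's theta requires n >= 2 chromosomes")
  sum(1 / seq_len(n - 1))
}

#' Windowed nucleotide diversity and Watterson's theta
#'
#' For each window, pi is the mean of per-site heterozygosity
#' ([site_heterozygosity()]) over *eligible* sites (monomorphic eligible
#' sites contribute 0 to the numerator and 1 to the denominator), and
#' theta = S / (a_{n-1} * n_eligible) where S is the number of SNP sites
#' in the window and a_{n-1} the harmonic sum for `n` sampled
#' chromosomes. Windows with no eligible sites get `NA`, not zero.
#'
#' @param x A `pool_sites` object.
#' @param windows `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open, end-exclusive), sorted and non-overlapping per chromosome.
#' @param filters A [filter_config()].
#' @param pools Pool scope whose summed counts define the estimates
#'   (default: all pools of `x`).
#' @param n_chromosomes Chromosomes sampled in the scope (e.g. 24 for a
#'   single pool of 12 diploid workers; the summed pool count for a
#'   merged stock track). Used only by theta.
#' @param caps Optional precomputed coverage caps.
#' @return `data.frame`: `chrom`, `start`, `end`, `n_eligible`, `n_snps`,
#'   `pi`, `theta`.
#' @export
window_stats <- function(x, windows, filters = filter_config(),
                         pools = NULL, n_chromosomes = 24, caps = NULL) {
  if (is.null(pools)) pools <- x$pools
  a <- watterson_a(n_chromosomes)
  cl <- classify_sites(x, filters, pools = pools, caps = caps)
  het <- site_heterozygosity(x, pools)
  widx <- assign_to_windows(x$chrom, x$pos, windows)

  n_win <- nrow(windows)
  n_eligible <- integer(n_win)
  n_snps <- integer(n_win)
  pi_sum <- numeric(n_win)
  in_win <- !is.na(widx)
  if (any(in_win)) {
    # sites with combined coverage < 2 have undefined pi-hat and are skipped
    el <- in_win & cl$sites$eligible & !is.na(het)
    n_eligible <- tabulate_at(widx[el], n_win)
    n_snps <- tabulate_at(widx[in_win & cl$sites$snp], n_win)
    pi_sum <- rowsum_at(het[el], widx[el], n_win)
  }
  pi <- ifelse(n_eligible > 0, pi_sum / n_eligible, NA_real_)
  theta <- ifelse(n_eligible > 0, n_snps / (a * n_eligible), NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             n_eligible = n_eligible, n_snps = n_snps, pi = pi, theta = theta,
             stringsAsFactors = FALSE)
}

tabulate_at <- function(idx, nbins) {
  if (length(idx) == 0L) return(integer(nbins))
  tabulate(idx, nbins)
}

rowsum_at <- function(values, idx, nbins) {
  out <- numeric(nbins)
  if (length(idx)) {
    s <- rowsum(values, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# window index per site (NA if in no window); windows sorted,
# non-overlapping per chromosome; membership start <= pos < end
assign_to_windows <- function(chrom, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(windows$chrom)) {
    w <- which(windows$chrom == ch)
    s <- windows$start[w]
    e <- windows$end[w]
    if (is.unsorted(s, strictly = FALSE)) {
      o <- order(s)
      w <- w[o]; s <- s[o]; e <- e[o]
    }
    if (any(e[-length(e)] > s[-1])) stop("windows overlap on ", ch)
    on_ch <- which(chrom == ch)
    if (!length(on_ch)) next
    k <- findInterval(pos[on_ch], s)
    hit <- k >= 1 & pos[on_ch] < e[pmax(k, 1)]
    idx[on_ch[hit]] <- w[k[hit]]
  }
  idx
}

#' Tile a region with fixed-size windows
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 0-based half-open.
#' @param size Window width in bp; the final window is truncated at `end`.
#' @return `data.frame` of windows.
#' @export
make_windows <- function(chrom, start, end, size) {
  starts <- seq(from = start, to = end - 1, by = size)
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + size, end), stringsAsFactors = FALSE)
}

#' Fixed-count window profile of diversity across a locus
#'
#' Partitions a locus (e.g. the honey bee *csd* sex-determination locus)
#' into `n_windows` equal-width nonoverlapping windows (the last window
#' absorbs the division remainder), computes per-window pi, and smooths
#' the profile with local linear regression over window midpoints.
#'
#' @param x A `pool_sites` object.
#' @param chrom Chromosome holding the locus.
#' @param start,end Locus bounds, 0-based half-open.
#' @param n_windows Number of windows (default 250).
#' @param filters A [filter_config()].
#' @param pools Pool scope (default all).
#' @param span `loess` span as a fraction of windows (default 0.3).
#' @param n_chromosomes Passed to [window_stats()] for the theta column.
#' @param caps Optional precomputed coverage caps.
#' @return `data.frame` of window stats plus `mid` and `pi_smooth`.
#' @export
locus_profile <- function(x, chrom, start, end, n_windows = 250,
                          filters = filter_config(), pools = NULL,
                          span = 0.3, n_chromosomes = 24, caps = NULL) {
  len <- end - start
  if (len < n_windows) {
    stop(sprintf("locus length %d < n_windows %d; choose fewer windows",
                 len, n_windows))
  }
  w <- len %/% n_windows
  starts <- start + (seq_len(n_windows) - 1L) * w
  ends <- starts + w
  ends[n_windows] <- end  # last window absorbs the remainder
  windows <- data.frame(chrom = chrom, start = starts, end = ends,
                        stringsAsFactors = FALSE)
  ws <- window_stats(x, windows, filters, pools = pools,
                     n_chromosomes = n_chromosomes, caps = caps)
  ws$mid <- (ws$start + ws$end) / 2
  ok <- !is.na(ws$pi)
  ws$pi_smooth <- NA_real_
  if (sum(ok) >= 4) {
    if (stats::var(ws$pi[ok]) == 0) {
      ws$pi_smooth[ok] <- ws$pi[ok]  # constant profile: smooth equals raw
    } else {
      fit <- stats::loess(pi ~ mid, data = ws[ok, ], span = span, degree = 1)
      ws$pi_smooth[ok] <- stats::predict(fit, ws$mid[ok])
    }
  } else {
    ws$pi_smooth[ok] <- ws$pi[ok]
  }
  ws
}
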
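#' Per-site classical FST from two count vectors
#'
#' The classical pi-based form: FST = (pi_total - pi_within) / pi_total
#' with pi_within = (pi_A + pi_B)/2 and pi_total the heterozygosity of
#' the summed counts, each per [site_heterozygosity()]. Sites whose
#' combined counts are monomorphic (pi_total = 0) are undefined (`NA`).
#' Negative values (pi_within > pi_total) are retained, not clamped:
#' clamping would distort genome-wide means.
#'
#' @param counts_a,counts_b Numeric matrices n x 4 of base counts in
#'   A,T,C,G order (or vectors of length 4 for a single site).
#' @return Numeric vector of per-site FST.
#' @export
site_fst <- function(counts_a, counts_b) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  pi_a <- site_pi_counts(counts_a)
  pi_b <- site_pi_counts(counts_b)
  pi_t <- site_pi_counts(counts_a + counts_b)
  pi_w <- (pi_a + pi_b) / 2
  ifelse(!is.na(pi_t) & pi_t > 0, (pi_t - pi_w) / pi_t, NA_real_)
}

#' Pairwise per-SNP FST scan across stocks
#'
#' Pools are first summed into one virtual track per stock (plus any
#' merged virtual stocks such as a generalized Italian background). For
#' each stock pair, sites are classified with scope = the two tracks
#' (eligibility: both coverages within `[min_coverage, cap]`; SNP:
#' combined minor-allele count >= `min_count`), and per-SNP FST is
#' computed at the SNP sites.
#'
#' @param x A `pool_sites` object.
#' @param panel A [pool_panel()].
#' @param pairs List of 2-element character vectors of stock names, or
#'   `NULL` for all pairs among `stocks`.
#' @param filters A [filter_config()].
#' @param merge Named list defining merged virtual stocks, e.g.
#'   `list(Italian = c("Italian1", "Italian2", "Italian3"))`.
#' @param stocks Stocks entering the default all-pairs set (default: all
#'   panel stocks plus merged ones).
#' @return Named list (`"A|B"`) of `fst_table` `data.frame`s with columns
#'   `chrom`, `pos`, `fst` and attribute `genome_mean` (unweighted mean
#'   of per-SNP FST; `NA` when the pair has no SNPs).
#' @export
pairwise_scan <- function(x, panel, pairs = NULL, filters = filter_config(),
                          merge = NULL, stocks = NULL) {
  tr <- stock_tracks(x, panel, merge = merge)
  if (is.null(stocks)) stocks <- tr$sites$pools
  unknown <- setdiff(stocks, tr$sites$pools)
  if (length(unknown)) stop("unknown stocks: ", paste(unknown, collapse = ", "))
  if (is.null(pairs)) {
    pairs <- utils::combn(stocks, 2, simplify = FALSE)
  }
  caps <- max_coverage_caps(tr$sites, filters)
  out <- lapply(pairs, function(pr) {
    cl <- classify_sites(tr$sites, filters, pools = pr, caps = caps)
    keep <- which(cl$sites$snp)
    ca <- combined_base_counts(tr$sites, pr[1])[keep, , drop = FALSE]
    cb <- combined_base_counts(tr$sites, pr[2])[keep, , drop = FALSE]
    fst <- site_fst(ca, cb)
    ok <- !is.na(fst)  # monomorphic combined sites skipped
    tbl <- data.frame(chrom = tr$sites$chrom[keep][ok],
                      pos = tr$sites$pos[keep][ok],
                      fst = fst[ok], stringsAsFactors = FALSE)
    attr(tbl, "pair") <- pr
    attr(tbl, "genome_mean") <- if (nrow(tbl)) mean(tbl$fst) else NA_real_
    class(tbl) <- c("fst_table", "data.frame")
    tbl
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "|")
  out
}

#' Genome-wide mean FST of a scan
#' @param tables Result of [pairwise_scan()].
#' @return Named numeric vector of unweighted per-SNP means.
#' @export
genome_mean_fst <- function(tables) {
  vapply(tables, function(t) attr(t, "genome_mean"), numeric(1))
}

#' SNPs with a high degree of fixed differentiation
#'
#' SNPs whose FST is strictly greater than the threshold (default 0.65).
#'
#' @param table An `fst_table`.
#' @param threshold FST threshold (default 0.65).
#' @return List with `count` and `snps` (subset of the table).
#' @export
fixed_differentiation <- function(table, threshold = 0.65) {
  hit <- table$fst > threshold
  list(count = sum(hit), snps = table[hit, , drop = FALSE])
}

#' Top-quantile SNP set of an FST table
#'
#' SNPs at or above the empirical `1 - q` quantile; ties at the cut are
#' included, so the set can slightly exceed `q x n`.
#'
#' @param table An `fst_table` (or any data.frame with an `fst` column).
#' @param q Upper-tail fraction, e.g. 0.01 or 0.001.
#' @return Subset of `table` with attributes `q` and `cutoff`.
#' @export
top_quantile <- function(table, q) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  cut <- stats::quantile(table$fst, probs = 1 - q, names = FALSE)
  out <- table[table$fst >= cut, , drop = FALSE]
  attr(out, "q") <- q
  attr(out, "cutoff") <- cut
  out
}

snp_key <- function(tbl) paste(tbl$chrom, tbl$pos, sep = ":")

#' Stock-specific SNPs from top-quantile sets
#'
#' Given top-`q` FST SNP sets for every pairwise comparison among a set
#' of stocks, a SNP is a *candidate* for stock `s` iff it lies in the
#' top set of every comparison involving `s` (rule `"every"`, the
#' default) or of at least one such comparison (rule `"any"`); it is
#' *stock-specific* iff it is a candidate for exactly one stock.
#'
#' @param tops Named list of top-quantile tables; names `"A|B"` as
#'   produced by applying [top_quantile()] over a [pairwise_scan()].
#' @param stocks Character vector of the stocks compared.
#' @param rule `"every"` (intersection across a stock's comparisons) or
#'   `"any"` (union).
#' @return Named list per stock of `data.frame(chrom, pos)` of
#'   stock-specific SNPs.
#' @export
stock_specific_snps <- function(tops, stocks, rule = c("every", "any")) {
  rule <- match.arg(rule)
  wanted <- utils::combn(stocks, 2, simplify = FALSE)
  key_of <- function(pr) {
    k1 <- paste(pr, collapse = "|")
    k2 <- paste(rev(pr), collapse = "|")
    if (k1 %in% names(tops)) k1 else if (k2 %in% names(tops)) k2 else NA_character_
  }
  keys <- vapply(wanted, key_of, character(1))
  if (anyNA(keys)) {
    miss <- vapply(wanted[is.na(keys)], paste, character(1), collapse = "|")
    stop("missing pairwise comparisons: ", paste(miss, collapse = ", "))
  }
  candidates <- lapply(stocks, function(s) {
    mine <- keys[vapply(wanted, function(pr) s %in% pr, logical(1))]
    sets <- lapply(tops[mine], snp_key)
    if (rule == "every") Reduce(intersect, sets) else Reduce(union, sets)
  })
  names(candidates) <- stocks
  all_keys <- unlist(candidates, use.names = FALSE)
  multi <- unique(all_keys[duplicated(all_keys)])
  out <- lapply(stocks, function(s) {
    k <- setdiff(candidates[[s]], multi)
    if (!length(k)) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(k, ":", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                     pos = as.integer(vapply(parts, `[`, character(1), 2)),
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$pos), , drop = FALSE]
  })
  names(out) <- stocks
  out
}
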
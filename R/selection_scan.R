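#' Fractional ranks
#'
#' Maps values into the open unit interval: r_i = rank_i / (N + 1) with
#' average ranks for ties, so all r lie strictly in (0, 1) and the
#' normal-quantile transform stays finite without clipping.
#'
#' @param values Numeric vector of finite values.
#' @return Numeric vector of fractional ranks.
#' @export
fractional_ranks <- function(values) {
  if (length(values) == 0L) stop("need at least one value")
  if (any(!is.finite(values))) stop("values must be finite")
  rank(values, ties.method = "average") / (length(values) + 1)
}

#' Normal-quantile transform of fractional ranks
#' @param r Numeric vector in the open interval (0, 1).
#' @return Standard-normal quantiles.
#' @export
rank_to_z <- function(r) {
  if (any(r <= 0 | r >= 1)) stop("fractional ranks must be strictly in (0, 1)")
  stats::qnorm(r)
}

#' Composite selection signal across population contrasts
#'
#' For each comparison's FST table, per-SNP fractional ranks are
#' transformed to Z-scores; the Z-scores are averaged across the m
#' comparisons per SNP. Under the null the mean of m independent
#' standard normals is Normal(0, 1/m), so the one-sided (high
#' differentiation) p-value is `p = 1 - Phi(zbar * sqrt(m))` and the
#' CSS score is `-log10(p)`.
#'
#' @param fst_tables Named list of `fst_table`s, one per comparison
#'   (e.g. each resistant stock vs the merged Italian background).
#' @param policy `"complete"` (default): a SNP must have an FST value in
#'   every comparison, others are dropped; `"available"`: SNPs present
#'   in any comparison are kept and scored with their own m.
#' @return `data.frame` of class `css_result`: `chrom`, `pos`, `z_mean`,
#'   `m`, `p`, `css`, plus one `z_<name>` column per comparison.
#' @export
css_score <- function(fst_tables, policy = c("complete", "available")) {
  policy <- match.arg(policy)
  if (length(fst_tables) < 1) stop("need at least one comparison")
  if (is.null(names(fst_tables))) {
    names(fst_tables) <- paste0("cmp", seq_along(fst_tables))
  }
  ztabs <- lapply(fst_tables, function(t) {
    data.frame(key = snp_key(t), z = rank_to_z(fractional_ranks(t$fst)),
               stringsAsFactors = FALSE)
  })
  keys <- unique(unlist(lapply(ztabs, `[[`, "key"), use.names = FALSE))
  zm <- matrix(NA_real_, length(keys), length(ztabs),
               dimnames = list(keys, names(fst_tables)))
  for (j in seq_along(ztabs)) {
    zm[match(ztabs[[j]]$key, keys), j] <- ztabs[[j]]$z
  }
  m_i <- rowSums(!is.na(zm))
  if (policy == "complete") {
    keep <- m_i == length(ztabs)
    zm <- zm[keep, , drop = FALSE]
    keys <- keys[keep]
    m_i <- m_i[keep]
  } else {
    keep <- m_i >= 1
    zm <- zm[keep, , drop = FALSE]
    keys <- keys[keep]
    m_i <- m_i[keep]
  }
  zbar <- rowMeans(zm, na.rm = TRUE)
  p <- stats::pnorm(zbar * sqrt(m_i), lower.tail = FALSE)
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    pos = as.integer(vapply(parts, `[`, character(1), 2)),
                    z_mean = zbar, m = m_i, p = p, css = -log10(p),
                    stringsAsFactors = FALSE)
  zcols <- as.data.frame(zm)
  names(zcols) <- paste0("z_", names(fst_tables))
  out <- cbind(out, zcols)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("css_result", "data.frame")
  out
}

#' CSS outliers in the upper tail
#'
#' SNPs whose CSS score is at or above the empirical `1 - q` quantile of
#' the CSS distribution; ties at the cut included.
#'
#' @param results A `css_result`.
#' @param q Upper-tail fraction (default 0.001, the top 0.1%).
#' @return Subset of `results` with attributes `q` and `cutoff`.
#' @export
top_css <- function(results, q = 0.001) {
  if (nrow(results) == 0L) stop("empty CSS table")
  cut <- stats::quantile(results$css, probs = 1 - q, names = FALSE)
  out <- results[results$css >= cut, , drop = FALSE]
  attr(out, "q") <- q
  attr(out, "cutoff") <- cut
  out
}

#' Localize CSS outliers to haplotype blocks
#'
#' Every scored SNP is assigned to each block containing it (membership
#' start <= pos < end, end-exclusive so abutting blocks never share a
#' SNP). A block is *reported* iff its total member-SNP count is
#' strictly greater than `min_snps_exclusive` and it contains at least
#' one outlier SNP.
#'
#' @param outliers Outlier SNPs ([top_css()] output).
#' @param all_snps All scored SNPs (the full `css_result`).
#' @param blocks Block table from [read_blocks_bed()].
#' @param min_snps_exclusive Blocks must exceed this SNP count to be
#'   reported (default 5, i.e. > 5 SNPs/block).
#' @return `data.frame`: `chrom`, `start`, `end`, `block_id`,
#'   `snp_count`, `outlier_count`, `reported`, sorted by position.
#' @export
map_to_blocks <- function(outliers, all_snps, blocks, min_snps_exclusive = 5) {
  # +1 keeps all coordinates positive for GRanges; the membership rule
  # start <= pos < end is unchanged by the common shift
  gr_blocks <- GenomicRanges::GRanges(
    blocks$chrom, IRanges::IRanges(start = blocks$start + 1L, end = blocks$end))
  count_in <- function(snps) {
    if (nrow(snps) == 0L) return(integer(nrow(blocks)))
    gr_snps <- GenomicRanges::GRanges(
      snps$chrom, IRanges::IRanges(start = snps$pos + 1L, width = 1L))
    GenomicRanges::countOverlaps(gr_blocks, gr_snps)
  }
  snp_count <- count_in(all_snps)
  outlier_count <- count_in(outliers)
  out <- data.frame(chrom = blocks$chrom, start = blocks$start,
                    end = blocks$end, block_id = blocks$block_id,
                    snp_count = snp_count, outlier_count = outlier_count,
                    reported = snp_count > min_snps_exclusive & outlier_count >= 1,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
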
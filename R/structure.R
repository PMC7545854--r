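#' Pool- and stock-level minor-allele frequency matrices
#'
#' Classifies sites with scope = the per-stock merged tracks, keeps SNP
#' sites, and returns minor-allele frequencies per pool (rows of the PCA
#' matrix) and per stock (used by the informative-SNP mask).
#'
#' @param x A `pool_sites` object.
#' @param panel A [pool_panel()].
#' @param filters A [filter_config()].
#' @return List: `info` (`data.frame` chrom, pos, major, minor),
#'   `pool_freq` (pools x SNPs), `stock_freq` (stocks x SNPs).
#' @export
snp_frequencies <- function(x, panel, filters = filter_config()) {
  tr <- stock_tracks(x, panel)
  cl <- classify_sites(tr$sites, filters)
  keep <- which(cl$sites$snp)
  stock_freq <- t(cl$freq[keep, , drop = FALSE])

  # per-pool frequency of the same minor allele
  n <- length(keep)
  minor_i <- match(cl$sites$minor[keep], SYNC_BASES)
  cov <- pool_coverage(x)[keep, , drop = FALSE]
  pool_freq <- vapply(seq_along(x$pools), function(j) {
    cj <- x$counts[keep, SYNC_BASES, j, drop = FALSE]
    dim(cj) <- c(n, 4L)
    mc <- cj[cbind(seq_len(n), minor_i)]
    ifelse(cov[, j] > 0, mc / cov[, j], NA_real_)
  }, numeric(n))
  dim(pool_freq) <- c(n, length(x$pools))
  pool_freq <- t(pool_freq)
  rownames(pool_freq) <- x$pools
  cn <- paste(cl$sites$chrom[keep], cl$sites$pos[keep], sep = ":")
  colnames(pool_freq) <- cn
  colnames(stock_freq) <- cn
  list(info = cl$sites[keep, c("chrom", "pos", "major", "minor")],
       pool_freq = pool_freq, stock_freq = stock_freq)
}

#' Keep SNPs informative for structure analysis
#'
#' A SNP column is retained iff at least one stock carries its minor
#' allele at a frequency strictly greater than `min_freq` (default 0.1).
#'
#' @param freqs Result of [snp_frequencies()].
#' @param min_freq Frequency threshold (strict inequality; default 0.1).
#' @return `freqs` with columns filtered in all three elements.
#' @export
select_informative_snps <- function(freqs, min_freq = 0.1) {
  mx <- apply(freqs$stock_freq, 2, max, na.rm = TRUE)
  keep <- which(is.finite(mx) & mx > min_freq)
  list(info = freqs$info[keep, , drop = FALSE],
       pool_freq = freqs$pool_freq[, keep, drop = FALSE],
       stock_freq = freqs$stock_freq[, keep, drop = FALSE])
}

#' PCA of a samples x SNPs frequency matrix
#'
#' Columns are mean-imputed where missing, centered, and decomposed by
#' SVD (via [stats::prcomp()], no scaling). Explained-variance fractions
#' are non-increasing and sum to at most 1.
#'
#' @param m Numeric matrix, rows = samples (pools), columns = SNPs.
#' @return List: `scores` (samples x PCs), `explained` (fractions),
#'   `sdev`.
#' @export
pca_frequencies <- function(m) {
  if (nrow(m) < 2) stop("PCA requires at least 2 samples")
  if (ncol(m) < 2) stop("PCA requires at least 2 SNPs")
  for (j in which(colSums(is.na(m)) > 0)) {
    mu <- mean(m[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0  # all-missing column centers to zero
    m[is.na(m[, j]), j] <- mu
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  list(scores = p$x, explained = v / sum(v), sdev = p$sdev)
}

#' AIC of k-means solutions over a range of k
#'
#' For each `k`, runs best-of-`restarts` k-means (squared Euclidean) on
#' the PC coordinates and scores it with the spherical-Gaussian AIC
#' `AIC(k) = n d ln(W_k / (n d)) + 2 k d`, where `W_k` is the total
#' within-cluster sum of squares, `n` the number of samples and `d` the
#' dimensionality. `W_k` is floored at 1e-12 so the degenerate k = n
#' solution (every point its own center) stays finite. Values of `k`
#' exceeding `n` are skipped with a warning.
#'
#' @param pcs Numeric matrix samples x dimensions.
#' @param k_range Integer vector of cluster counts (default 1:10).
#' @param restarts `nstart` for [stats::kmeans()] (default 25).
#' @param seed Optional integer; when given, results are deterministic.
#' @return List: `aic` (`data.frame` k, W, AIC) and `clusters` (list of
#'   assignment vectors named by k).
#' @export
kmeans_aic <- function(pcs, k_range = 1:10, restarts = 25, seed = NULL) {
  if (restarts < 1) stop("restarts must be >= 1")
  pcs <- as.matrix(pcs)
  if (any(!is.finite(pcs))) stop("PC coordinates must be finite")
  n <- nrow(pcs)
  d <- ncol(pcs)
  run <- function() {
    keep <- k_range[k_range <= n]
    if (length(keep) < length(k_range)) {
      warning(sprintf("skipping k > n (= %d): %s", n,
                      paste(setdiff(k_range, keep), collapse = ", ")))
    }
    row_key <- apply(pcs, 1, paste, collapse = "\r")
    n_distinct <- length(unique(row_key))
    res <- lapply(keep, function(k) {
      if (k >= n_distinct) {
        # degenerate solution: a center on every distinct point, W = 0 (floored)
        cluster <- match(row_key, unique(row_key))
        W <- 1e-12
      } else {
        km <- suppressWarnings(
          stats::kmeans(pcs, centers = k, nstart = restarts, iter.max = 100))
        W <- max(sum(km$withinss), 1e-12)
        cluster <- km$cluster
      }
      list(k = k, W = W, aic = n * d * log(W / (n * d)) + 2 * k * d,
           cluster = cluster)
    })
    list(
      aic = data.frame(k = vapply(res, `[[`, numeric(1), "k"),
                       W = vapply(res, `[[`, numeric(1), "W"),
                       AIC = vapply(res, `[[`, numeric(1), "aic")),
      clusters = stats::setNames(lapply(res, `[[`, "cluster"),
                                 vapply(res, `[[`, numeric(1), "k"))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Choose the number of clusters by the elbow of the AIC curve
#'
#' The chosen k maximizes the discrete second difference
#' `AIC(k-1) - 2 AIC(k) + AIC(k+1)` over interior points; ties resolve
#' to the smallest k. With fewer than three AIC values the elbow is
#' undefined and the argmin of AIC is returned with a warning.
#'
#' @param aic `data.frame` with columns `k` and `AIC` (as from
#'   [kmeans_aic()]), ordered by k.
#' @return The chosen integer k.
#' @export
choose_k_elbow <- function(aic) {
  aic <- aic[order(aic$k), , drop = FALSE]
  if (nrow(aic) < 3) {
    warning("fewer than 3 AIC points: falling back to argmin AIC")
    return(aic$k[which.min(aic$AIC)])
  }
  a <- aic$AIC
  d2 <- a[-c(length(a) - 1, length(a))] - 2 * a[-c(1, length(a))] + a[-(1:2)]
  aic$k[-c(1, nrow(aic))][which.max(d2)]  # which.max: first max = smallest k
}

#' PCA + k-means/AIC structure analysis of pool frequencies
#'
#' The full structure stage: build the informative-SNP frequency matrix,
#' run PCA over pools, cluster the leading PCs with k-means over a range
#' of k, score with AIC and pick k by the elbow rule.
#'
#' @param x A `pool_sites` object.
#' @param panel A [pool_panel()].
#' @param filters A [filter_config()].
#' @param min_freq Informative-SNP threshold (default 0.1).
#' @param k_range Candidate cluster counts (default 1:10).
#' @param restarts k-means restarts (default 25).
#' @param n_pcs Number of PCs fed to clustering; default: the smallest
#'   number covering 90% of variance (at least 2).
#' @param seed Integer seed for the k-means restarts.
#' @return List of class `cluster_result`: `scores`, `explained`,
#'   `n_pcs`, `aic`, `k`, `assignment` (named by pool).
#' @export
structure_scan <- function(x, panel, filters = filter_config(),
                           min_freq = 0.1, k_range = 1:10, restarts = 25,
                           n_pcs = NULL, seed = 1L) {
  freqs <- select_informative_snps(snp_frequencies(x, panel, filters),
                                   min_freq = min_freq)
  p <- pca_frequencies(freqs$pool_freq)
  if (is.null(n_pcs)) {
    n_pcs <- max(2L, which(cumsum(p$explained) >= 0.9)[1])
  }
  n_pcs <- min(n_pcs, ncol(p$scores))
  ka <- kmeans_aic(p$scores[, seq_len(n_pcs), drop = FALSE],
                   k_range = k_range, restarts = restarts, seed = seed)
  k <- choose_k_elbow(ka$aic)
  structure(list(scores = p$scores, explained = p$explained, n_pcs = n_pcs,
                 aic = ka$aic, k = k,
                 assignment = ka$clusters[[as.character(k)]],
                 n_snps = ncol(freqs$pool_freq)),
            class = "cluster_result")
}
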
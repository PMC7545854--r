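# sync dialect: tab-separated "chrom pos ref A:T:C:G:N:del x(n pools)",
# count order fixed to Popoolation2's A:T:C:G:N:del.

SYNC_BASES <- c("A", "T", "C", "G")
SYNC_COLS <- c("A", "T", "C", "G", "N", "del")

#' Describe the pools of a pool-seq experiment
#'
#' A pool panel maps each sync column to a pool label, the stock (population)
#' the pool was drawn from, and the number of chromosomes sampled into the
#' pool (2 x number of diploid individuals; 24 for pools of 12 workers).
#'
#' @param pool Character vector of unique pool labels, in sync column order.
#' @param stock Character vector, same length: stock membership per pool.
#' @param n_chromosomes Integer, chromosomes per pool (recycled). Default 24.
#' @return A `data.frame` of class `pool_panel` with columns
#'   `pool`, `stock`, `n_chromosomes`.
#' @examples
#' pool_panel(c("A_p1", "A_p2", "B_p1"), c("A", "A", "B"))
#' @export
pool_panel <- function(pool, stock, n_chromosomes = 24L) {
  pool <- as.character(pool)
  stock <- as.character(stock)
  if (length(pool) != length(stock)) {
    stop("'pool' and 'stock' must have the same length")
  }
  if (anyDuplicated(pool)) {
    stop("pool labels must be unique")
  }
  n_chromosomes <- as.integer(rep_len(n_chromosomes, length(pool)))
  if (any(n_chromosomes < 2L)) stop("n_chromosomes must be >= 2")
  structure(
    data.frame(pool = pool, stock = stock, n_chromosomes = n_chromosomes,
               stringsAsFactors = FALSE),
    class = c("pool_panel", "data.frame")
  )
}

#' Per-site per-pool nucleotide counts
#'
#' The in-memory representation of a sync table: site coordinates plus an
#' integer count array of dimension sites x 6 (A,T,C,G,N,del) x pools.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref Character vector of reference bases (A,C,G,T or N).
#' @param counts Integer array `[n_sites, 6, n_pools]`; the middle dimension
#'   follows the sync order A:T:C:G:N:del.
#' @param pools Character vector of pool labels for the third dimension.
#' @return An object of class `pool_sites`.
#' @export
pool_sites <- function(chrom, pos, ref, counts, pools = NULL) {
  n <- length(chrom)
  pos <- as.integer(pos)
  if (length(pos) != n || length(ref) != n) {
    stop("chrom, pos and ref must have equal length")
  }
  if (any(pos < 1L)) stop("positions are 1-based and must be >= 1")
  if (length(dim(counts)) != 3L || dim(counts)[1] != n || dim(counts)[2] != 6L) {
    stop("counts must be an n_sites x 6 x n_pools array")
  }
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be non-negative")
  if (is.null(pools)) pools <- dimnames(counts)[[3]]
  if (is.null(pools)) pools <- paste0("pool", seq_len(dim(counts)[3]))
  dimnames(counts) <- list(NULL, SYNC_COLS, pools)
  structure(
    list(chrom = as.character(chrom), pos = pos, ref = as.character(ref),
         counts = counts, pools = pools),
    class = "pool_sites"
  )
}

#' @export
print.pool_sites <- function(x, ...) {
  cat(sprintf("pool_sites: %d sites x %d pools (%s)\n",
              length(x$pos), length(x$pools),
              paste(utils::head(unique(x$chrom), 4), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a `pool_sites` object
#' @param x A `pool_sites` object.
#' @export
n_sites <- function(x) length(x$pos)

#' Per-pool read coverage
#'
#' Coverage is the sum of the four base counts A+T+C+G; N and deletion
#' counts are excluded, matching the base-count semantics of the
#' diversity and differentiation estimators downstream.
#'
#' @param x A `pool_sites` object.
#' @return Integer matrix sites x pools.
#' @export
pool_coverage <- function(x) {
  n <- length(x$pos)
  cov <- vapply(seq_along(x$pools), function(j) {
    cj <- x$counts[, SYNC_BASES, j, drop = FALSE]
    dim(cj) <- c(n, 4L)
    rowSums(cj)
  }, numeric(n))
  dim(cov) <- c(n, length(x$pools))
  colnames(cov) <- x$pools
  cov
}

#' Read a Popoolation2-style sync table
#'
#' @param path Path to a tab-separated sync file.
#' @param panel A [pool_panel()]; its size must match the file's pool columns.
#' @return A [pool_sites()] object with pools labelled from `panel`.
#' @export
read_sync <- function(path, panel) {
  lines <- readLines(path)
  npool <- nrow(panel)
  n <- length(lines)
  if (n == 0L) {
    return(pool_sites(character(0), integer(0), character(0),
                      array(integer(0), c(0, 6, npool)), pools = panel$pool))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L + npool)
  if (length(bad)) {
    stop(sprintf("sync line %d: expected %d columns (3 + %d pools), found %d",
                 bad[1], 3L + npool, npool, nf[bad[1]]))
  }
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    stop(sprintf("sync line %d: non-integer position '%s'",
                 which(is.na(pos))[1], m[which(is.na(pos))[1], 2]))
  }
  counts <- array(0L, c(n, 6, npool))
  for (j in seq_len(npool)) {
    parts <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      stop(sprintf("sync line %d: malformed count field '%s' (need 6 ':' fields)",
                   which(lengths(parts) != 6L)[1], m[which(lengths(parts) != 6L)[1], 3L + j]))
    }
    cj <- suppressWarnings(matrix(as.integer(unlist(parts)), nrow = 6))
    if (anyNA(cj)) {
      stop(sprintf("sync line %d: non-integer count in pool column %d",
                   which(colSums(is.na(cj)) > 0)[1], j))
    }
    counts[, , j] <- t(cj)
  }
  pool_sites(m[, 1], pos, m[, 3], counts, pools = panel$pool)
}

#' Write a sync table
#'
#' Inverse of [read_sync()]; the round trip is byte-identical.
#'
#' @param x A `pool_sites` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  n <- length(x$pos)
  if (n == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write sync file: ", path)
    return(invisible(path))
  }
  poolcols <- vapply(seq_along(x$pools), function(j) {
    cj <- x$counts[, , j, drop = FALSE]
    dim(cj) <- c(n, 6)
    do.call(paste, c(lapply(seq_len(6), function(b) cj[, b]), sep = ":"))
  }, character(n))
  dim(poolcols) <- c(n, length(x$pools))
  lines <- do.call(paste, c(list(x$chrom, x$pos, x$ref),
                            lapply(seq_along(x$pools), function(j) poolcols[, j]),
                            sep = "\t"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read haplotype blocks from a BED file
#'
#' BED is 0-based half-open. Blocks are returned sorted by
#' (chromosome, start); overlapping blocks are accepted and not merged.
#'
#' @param path Path to a BED3+ file (tab-separated, no header).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `block_id`.
#' @export
read_blocks_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), block_id = character(0),
                      stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$chrom <- as.character(bed$chrom)
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  bad <- which(bed$start >= bed$end)
  if (length(bad)) {
    stop(sprintf("BED record %d: start (%d) must be < end (%d)",
                 bad[1], bed$start[bad[1]], bed$end[bad[1]]))
  }
  if (ncol(bed) >= 4) {
    names(bed)[4] <- "block_id"
    bed$block_id <- as.character(bed$block_id)
  } else {
    bed$block_id <- sprintf("block_%05d", seq_len(nrow(bed)))
  }
  bed <- bed[order(bed$chrom, bed$start, bed$end), c("chrom", "start", "end", "block_id")]
  rownames(bed) <- NULL
  bed
}

#' Write intervals as BED
#' @param x `data.frame` with columns `chrom`, `start`, `end` and optionally
#'   an id column written as the BED name field.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  idcol <- intersect(c("block_id", "id", "name"), names(x))
  if (length(idcol)) cols <- c(cols, list(x[[idcol[1]]]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Extract per-sample alternate-allele frequencies from a VCF
#'
#' Uses the per-sample `AD` (allelic depths) field when present, falling
#' back to a per-sample `AF` field. Missing sample fields yield `NA`,
#' never a fabricated frequency.
#'
#' @param path Path to a VCF 4.x file.
#' @param panel Optional [pool_panel()]; if given, sample names must match
#'   the panel's pool labels.
#' @return A list with `sites` (`data.frame` of chrom, pos, ref, alt) and
#'   `freq` (numeric matrix sites x samples of alt-allele frequencies).
#' @export
read_vcf_frequencies <- function(path, panel = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-variant files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, element = "AD")
    split_ad <- function(s) {
      if (is.na(s) || s == "." || s == "") return(NA_real_)
      p <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
      if (length(p) < 2 || anyNA(p) || sum(p) == 0) return(NA_real_)
      p[2] / sum(p)
    }
    freq <- apply(ad, c(1, 2), split_ad)
    samples <- colnames(ad)
  } else if ("AF" %in% fmt) {
    freq <- vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)
    samples <- colnames(freq)
  } else {
    stop("unsupported VCF: no per-sample AD or AF field in FORMAT")
  }
  freq <- matrix(as.numeric(freq), nrow = nrow(fix),
                 dimnames = list(NULL, samples))
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) {
    stop("VCF frequencies outside [0,1]")
  }
  if (!is.null(panel)) {
    missing_pools <- setdiff(panel$pool, colnames(freq))
    if (length(missing_pools)) {
      stop("VCF lacks samples for pools: ", paste(missing_pools, collapse = ", "))
    }
    freq <- freq[, panel$pool, drop = FALSE]
  }
  list(
    sites = data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       stringsAsFactors = FALSE),
    freq = freq
  )
}

# single package-wide interval rule, end-exclusive: a position belongs to
# [start, end) iff start <= pos < end. Used for blocks, windows and
# selected regions so abutting intervals never double-count a boundary site.
in_interval <- function(pos, start, end) {
  pos >= start & pos < end
}

#' Subset sites of a `pool_sites` object
#' @param x A `pool_sites` object.
#' @param i Logical or integer site index.
#' @param pools Optional character or integer pool selection.
#' @export
subset_sites <- function(x, i = NULL, pools = NULL) {
  if (is.null(i)) i <- seq_along(x$pos)
  if (is.null(pools)) pools <- x$pools
  pool_sites(x$chrom[i], x$pos[i], x$ref[i],
             x$counts[i, , pools, drop = FALSE],
             pools = if (is.character(pools)) pools else x$pools[pools])
}
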
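#' Configuration of the pool-seq simulator
#'
#' Defines a study layout mirroring a multi-stock pool-seq experiment:
#' `n_stocks` populations, each sequenced as `pools_per_stock` pools of
#' `pool_chromosomes`/2 diploid workers (24 chromosomes for pools of 12
#' heads), at a mean per-pool depth of `depth_mean` reads (default 30x).
#' Among-stock divergence follows a Balding-Nichols model with drift
#' parameter `drift_F`; "selected" regions shift the allele frequencies
#' of a designated stock subset.
#'
#' @param n_stocks Number of stocks (default 8).
#' @param pools_per_stock Pools sequenced per stock (default 12).
#' @param pool_chromosomes Chromosomes per pool (default 24).
#' @param n_sites Number of simulated biallelic sites.
#' @param depth_mean Mean Poisson read depth per pool per site (default 30).
#' @param seq_error Per-read probability of miscalling to a uniformly
#'   chosen other base (default 0.001).
#' @param drift_F Balding-Nichols drift parameter in [0, 1), scalar or
#'   one value per stock (default 0.05).
#' @param n_chromosomes Number of simulated chromosomes/linkage groups
#'   (default 1), named `LG1`, `LG2`, ...
#' @param site_spacing Base pairs between adjacent sites (default 100).
#' @param ancestral_shape Length-2 Beta shape pair for the ancestral
#'   allele-frequency distribution (default `c(0.5, 0.5)`, a U-shaped
#'   spectrum concentrating mass near fixation as observed SNP panels do).
#' @param selected_regions `NULL` or a `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `freq_shift`, `stocks`
#'   (comma-separated stock names); regions must not overlap within a
#'   chromosome.
#' @param stock_names Stock labels (default `stock1..stockN`).
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_stocks = 8, pools_per_stock = 12,
                       pool_chromosomes = 24, n_sites = 1000,
                       depth_mean = 30, seq_error = 0.001, drift_F = 0.05,
                       n_chromosomes = 1, site_spacing = 100,
                       ancestral_shape = c(0.5, 0.5),
                       selected_regions = NULL, stock_names = NULL,
                       seed = 1L) {
  if (pool_chromosomes < 2) stop("pool_chromosomes must be >= 2")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (seq_error < 0 || seq_error > 1) stop("seq_error must be in [0, 1]")
  drift_F <- rep_len(drift_F, n_stocks)
  if (any(drift_F < 0) || any(drift_F >= 1)) {
    stop("drift_F must lie in [0, 1)")
  }
  if (any(ancestral_shape <= 0) || length(ancestral_shape) != 2) {
    stop("ancestral_shape must be two positive Beta shapes")
  }
  if (is.null(stock_names)) stock_names <- paste0("stock", seq_len(n_stocks))
  if (length(stock_names) != n_stocks || anyDuplicated(stock_names)) {
    stop("stock_names must be n_stocks unique labels")
  }
  chroms <- paste0("LG", seq_len(n_chromosomes))
  if (!is.null(selected_regions)) {
    need <- c("chrom", "start", "end", "freq_shift", "stocks")
    if (!all(need %in% names(selected_regions))) {
      stop("selected_regions needs columns: ", paste(need, collapse = ", "))
    }
    if (any(selected_regions$start >= selected_regions$end)) {
      stop("selected region start must be < end")
    }
    for (ch in unique(selected_regions$chrom)) {
      r <- selected_regions[selected_regions$chrom == ch, ]
      r <- r[order(r$start), ]
      if (nrow(r) > 1 && any(r$end[-nrow(r)] > r$start[-1])) {
        stop("selected regions overlap on ", ch)
      }
    }
    reg_stocks <- unlist(strsplit(selected_regions$stocks, ",", fixed = TRUE))
    bad <- setdiff(trimws(reg_stocks), stock_names)
    if (length(bad)) stop("selected_regions name unknown stocks: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_stocks = as.integer(n_stocks),
    pools_per_stock = as.integer(pools_per_stock),
    pool_chromosomes = as.integer(pool_chromosomes),
    n_sites = as.integer(n_sites), depth_mean = depth_mean,
    seq_error = seq_error, drift_F = drift_F,
    n_chromosomes = as.integer(n_chromosomes),
    site_spacing = as.integer(site_spacing),
    ancestral_shape = ancestral_shape,
    selected_regions = selected_regions,
    stock_names = stock_names, chroms = chroms, seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic genome layout: sites split near-evenly across chromosomes,
# evenly spaced at site_spacing
site_coordinates <- function(config) {
  per <- rep(config$n_sites %/% config$n_chromosomes, config$n_chromosomes)
  extra <- config$n_sites %% config$n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(config$chroms, per)
  pos <- unlist(lapply(per, function(k) config$site_spacing * seq_len(k)),
                use.names = FALSE)
  data.frame(chrom = chrom, pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' Pool panel implied by a simulation configuration
#' @param config A [sim_config()].
#' @return A [pool_panel()] with labels `<stock>_p<i>`.
#' @export
panel_from_config <- function(config) {
  stock <- rep(config$stock_names, each = config$pools_per_stock)
  pool <- paste0(stock, "_p", rep(seq_len(config$pools_per_stock),
                                  config$n_stocks))
  pool_panel(pool, stock, n_chromosomes = config$pool_chromosomes)
}

#' Simulate per-stock allele frequencies under Balding-Nichols drift
#'
#' Ancestral frequencies p are drawn from the configured Beta spectrum;
#' each stock's frequency is drawn from
#' Beta(p (1-F)/F, (1-p) (1-F)/F), whose variance is F p (1-p).
#' `F = 0` returns the ancestral frequency exactly (no division by F).
#'
#' @param config A [sim_config()].
#' @return A `truth_table`: `data.frame` with `chrom`, `pos`,
#'   `p_ancestral`, `selected` (all `FALSE` here) and one frequency
#'   column per stock, plus attribute `stocks`.
#' @export
simulate_stock_frequencies <- function(config) {
  coords <- site_coordinates(config)
  n <- config$n_sites
  withr::with_seed(config$seed, {
    p <- stats::rbeta(n, config$ancestral_shape[1], config$ancestral_shape[2])
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    freqs <- vapply(seq_len(config$n_stocks), function(s) {
      F <- config$drift_F[s]
      if (F == 0) p
      else stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }, numeric(n))
  })
  dim(freqs) <- c(n, config$n_stocks)
  colnames(freqs) <- config$stock_names
  out <- data.frame(coords, p_ancestral = p, selected = FALSE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(freqs))
  attr(out, "stocks") <- config$stock_names
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Plant selection signals into a truth table
#'
#' Inside each configured selected region, the frequencies of the
#' affected stocks are shifted by `freq_shift` (clipped to [0, 1]) and
#' the `selected` flag is set; unaffected stocks are untouched.
#'
#' @param truth A `truth_table` from [simulate_stock_frequencies()].
#' @param config The same [sim_config()].
#' @return The modified `truth_table`.
#' @export
inject_selection <- function(truth, config) {
  regions <- config$selected_regions
  if (is.null(regions) || nrow(regions) == 0L) return(truth)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!r$chrom %in% config$chroms) {
      stop("selected region on unknown chromosome: ", r$chrom)
    }
    max_pos <- max(truth$pos[truth$chrom == r$chrom])
    if (r$start >= max_pos) {
      stop(sprintf("selected region %s:[%d,%d) lies outside simulated coordinates",
                   r$chrom, r$start, r$end))
    }
    hit <- truth$chrom == r$chrom & in_interval(truth$pos, r$start, r$end)
    affected <- trimws(strsplit(r$stocks, ",", fixed = TRUE)[[1]])
    for (s in affected) {
      truth[[s]][hit] <- pmin(pmax(truth[[s]][hit] + r$freq_shift, 0), 1)
    }
    truth$selected[hit] <- TRUE
  }
  truth
}

#' Simulate pooled sequencing reads from a truth table
#'
#' Two-stage pool-seq sampling per pool per site: (1) the allele count
#' in the pool is binomial with `pool_chromosomes` trials at the stock
#' frequency (the pool-size variance floor); (2) read depth is Poisson
#' with mean `depth_mean`; (3) read allele counts are binomial at the
#' pool's realized frequency; (4) each read is miscalled to a uniformly
#' chosen other base with probability `seq_error`. Each site is
#' biallelic in truth (a reference and an alternate base drawn at
#' random); errors can create third alleles.
#'
#' @param truth A `truth_table` (frequencies are of the alternate base).
#' @param config A [sim_config()].
#' @return List: `sites` (a [pool_sites()] of sync-compatible counts),
#'   `panel` (the [pool_panel()]), `truth`.
#' @export
simulate_pool_reads <- function(truth, config) {
  n <- nrow(truth)
  panel <- panel_from_config(config)
  npool <- nrow(panel)
  counts <- array(0L, c(n, 6L, npool),
                  dimnames = list(NULL, SYNC_COLS, panel$pool))
  withr::with_seed(config$seed + 1L, {
    ref_i <- sample.int(4L, n, replace = TRUE)
    alt_i <- vapply(ref_i, function(r) sample(setdiff(1:4, r), 1L), integer(1))
    e <- config$seq_error
    for (j in seq_len(npool)) {
      f_stock <- truth[[panel$stock[j]]]
      k <- stats::rbinom(n, config$pool_chromosomes, f_stock)
      f_pool <- k / config$pool_chromosomes
      depth <- stats::rpois(n, config$depth_mean)
      n_alt <- stats::rbinom(n, depth, f_pool)
      n_ref <- depth - n_alt
      acc <- matrix(0L, n, 4L)
      for (origin in c("ref", "alt")) {
        n_o <- if (origin == "ref") n_ref else n_alt
        o_i <- if (origin == "ref") ref_i else alt_i
        stay <- stats::rbinom(n, n_o, 1 - e)
        mis <- n_o - stay
        # spread miscalls uniformly over the three other bases
        m1 <- stats::rbinom(n, mis, 1 / 3)
        m2 <- stats::rbinom(n, mis - m1, 1 / 2)
        m3 <- mis - m1 - m2
        others <- rbind(o_i %% 4L + 1L, (o_i + 1L) %% 4L + 1L,
                        (o_i + 2L) %% 4L + 1L)
        acc[cbind(seq_len(n), o_i)] <- acc[cbind(seq_len(n), o_i)] + stay
        acc[cbind(seq_len(n), others[1, ])] <- acc[cbind(seq_len(n), others[1, ])] + m1
        acc[cbind(seq_len(n), others[2, ])] <- acc[cbind(seq_len(n), others[2, ])] + m2
        acc[cbind(seq_len(n), others[3, ])] <- acc[cbind(seq_len(n), others[3, ])] + m3
      }
      counts[, 1:4, j] <- acc
    }
  })
  sites <- pool_sites(truth$chrom, truth$pos, SYNC_BASES[ref_i], counts,
                      pools = panel$pool)
  list(sites = sites, panel = panel, truth = truth)
}

#' Write a complete simulated fixture set
#'
#' Runs the generator end to end and writes four files: `counts.sync`,
#' `blocks.bed` (haplotype blocks with lengths drawn uniformly within
#' 287-17663 bp), `truth.tsv`, and `config.yml` (the configuration
#' echo). Byte-identical across runs at a fixed seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @return Named character vector of the four paths, invisibly.
#' @export
emit_fixtures <- function(config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  truth <- inject_selection(simulate_stock_frequencies(config), config)
  sim <- simulate_pool_reads(truth, config)
  paths <- c(sync = file.path(out_dir, "counts.sync"),
             blocks = file.path(out_dir, "blocks.bed"),
             truth = file.path(out_dir, "truth.tsv"),
             config = file.path(out_dir, "config.yml"))
  tryCatch({
    write_sync(sim$sites, paths["sync"])
    write_bed(simulate_blocks(config), paths["blocks"])
    utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(yaml::as.yaml(unclass(config)[setdiff(names(config), "chroms")]),
               paths["config"])
  }, error = function(e) {
    stop("writing fixtures under '", out_dir, "' failed: ", conditionMessage(e))
  })
  invisible(paths)
}

#' Simulate haplotype blocks along the genome
#'
#' Blocks tile each chromosome with uniform gaps; lengths are drawn
#' uniformly within `length_range` (default the 287-17663 bp span of
#' empirically derived honey bee haplotype blocks).
#'
#' @param config A [sim_config()].
#' @param length_range Two-element integer range of block lengths.
#' @param gap_range Two-element integer range of inter-block gaps.
#' @return `data.frame` of blocks (`chrom`, `start`, `end`, `block_id`).
#' @export
simulate_blocks <- function(config, length_range = c(287L, 17663L),
                            gap_range = c(0L, 2000L)) {
  per <- table(factor(site_coordinates(config)$chrom, levels = config$chroms))
  withr::with_seed(config$seed + 2L, {
    out <- lapply(config$chroms, function(ch) {
      chrom_len <- (per[[ch]] + 1L) * config$site_spacing
      starts <- integer(0)
      ends <- integer(0)
      cursor <- 0L
      repeat {
        gap <- as.integer(floor(stats::runif(1, gap_range[1], gap_range[2] + 1)))
        len <- as.integer(floor(stats::runif(1, length_range[1], length_range[2] + 1)))
        if (cursor + gap + len > chrom_len) break
        starts <- c(starts, cursor + gap)
        ends <- c(ends, cursor + gap + len)
        cursor <- cursor + gap + len
      }
      data.frame(chrom = rep(ch, length(starts)), start = starts, end = ends,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, out)
  out$block_id <- sprintf("block_%05d", seq_len(nrow(out)))
  out
}

#' Evenly spaced selected regions covering a fraction of the genome
#'
#' Convenience constructor for planted-selection studies: `n_regions`
#' equal-length regions placed evenly along the first chromosome so that
#' together they cover `fraction` of the simulated sites.
#'
#' @param config A [sim_config()] (without regions).
#' @param stocks Character vector of affected stocks.
#' @param freq_shift Frequency shift applied inside regions.
#' @param fraction Fraction of sites covered (default 0.01).
#' @param n_regions Number of regions (default 10).
#' @return A `selected_regions` `data.frame` for [sim_config()].
#' @export
place_selected_regions <- function(config, stocks, freq_shift,
                                   fraction = 0.01, n_regions = 10) {
  coords <- site_coordinates(config)
  ch <- config$chroms[1]
  on_ch <- coords[coords$chrom == ch, ]
  n_sel <- max(1L, round(fraction * nrow(coords)))
  per_region <- max(1L, n_sel %/% n_regions)
  n_regions <- max(1L, n_sel %/% per_region)
  anchor_idx <- floor(seq(1, nrow(on_ch) - per_region,
                          length.out = n_regions))
  starts <- on_ch$pos[anchor_idx] - 1L
  ends <- on_ch$pos[anchor_idx + per_region - 1L] + 1L
  data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
             freq_shift = freq_shift,
             stocks = paste(stocks, collapse = ","),
             stringsAsFactors = FALSE)
}
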
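# resolved defaults; every threshold the stages use lives here, never
# hard-coded inside a stage
config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "poolscan_out",
    inputs = list(sync = NULL, panel = NULL, blocks = NULL),
    simulate = NULL,
    filters = list(min_coverage = 20, min_count = 10, min_quality = 20,
                   max_cov_percentile = 98),
    diversity = list(window_size = 10000, locus = NULL, n_windows = 250),
    fst = list(fixed_threshold = 0.65, top_q = c(0.01, 0.001),
               merge = NULL, pairs = "all"),
    structure = list(min_freq = 0.1, k_min = 1, k_max = 10, restarts = 25,
                     n_pcs = NULL),
    css = list(enabled = TRUE, comparisons = NULL, top_q = 0.001,
               min_block_snps = 5)
  )
}

#' Validate and resolve a run configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys and basic
#' type/bound violations are collected and reported together. All
#' defaults (min coverage 20, min count 10, fixed-differentiation 0.65,
#' top quantiles 1% and 0.1%, CSS quantile 0.1%, k range 1-10, 250
#' locus windows) are resolved into the returned object.
#'
#' @param config Path to a YAML file, or a (possibly partial) list.
#' @return A fully resolved list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- config_defaults()
  errors <- character(0)

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (sect in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sect]]) && is.list(config[[sect]])) {
      bad <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
      if (length(bad)) {
        errors <- c(errors, paste0("unknown key(s) in '", sect, "': ",
                                   paste(bad, collapse = ", ")))
      }
    }
  }
  merged <- utils::modifyList(defaults, config)

  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(merged$filters$min_coverage >= 1, "filters$min_coverage must be >= 1")
  chk(merged$filters$min_count >= 1, "filters$min_count must be >= 1")
  chk(merged$filters$max_cov_percentile > 0 &&
        merged$filters$max_cov_percentile <= 100,
      "filters$max_cov_percentile must be in (0, 100]")
  chk(merged$fst$fixed_threshold >= 0, "fst$fixed_threshold must be >= 0")
  chk(all(merged$fst$top_q > 0 & merged$fst$top_q <= 1),
      "fst$top_q values must be in (0, 1]")
  chk(merged$css$top_q > 0 && merged$css$top_q <= 1,
      "css$top_q must be in (0, 1]")
  chk(merged$structure$k_min >= 1 &&
        merged$structure$k_max >= merged$structure$k_min,
      "structure k range invalid")
  chk(is.numeric(merged$seed) && length(merged$seed) == 1,
      "seed must be a single integer")
  for (f in c("sync", "panel", "blocks")) {
    p <- merged$inputs[[f]]
    if (!is.null(p) && !file.exists(p)) {
      errors <- c(errors, paste0("inputs$", f, " does not exist: ", p))
    }
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  merged$seed <- as.integer(merged$seed)
  class(merged) <- "run_config"
  merged
}

#' Read a pool panel from a TSV file
#'
#' Expects a header with columns `pool`, `stock` and optionally
#' `n_chromosomes`.
#'
#' @param path Path to the TSV file.
#' @return A [pool_panel()].
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("pool", "stock") %in% names(tab))) {
    stop("panel file needs 'pool' and 'stock' columns: ", path)
  }
  nc <- if ("n_chromosomes" %in% names(tab)) tab$n_chromosomes else 24L
  pool_panel(tab$pool, tab$stock, n_chromosomes = nc)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pool-seq analysis pipeline
#'
#' Executes the stages in dependency order — data (simulate or load),
#' filters/caps, windowed diversity per stock, pairwise FST (with
#' fixed-differentiation counts, top-quantile and stock-specific SNP
#' sets), PCA/k-means structure, and the CSS scan with block
#' localization — writing one TSV per result and a JSON manifest with
#' parameters, seed and MD5 checksums. Re-running an identical
#' configuration reproduces identical outputs.
#'
#' @param config A `run_config` (or anything [validate_config()] accepts).
#' @return The manifest, invisibly (list with `outputs`, `parameters`,
#'   `counts`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(if (inherits(config, "run_config")) {
    unclass(config)
  } else config)
  # fail fast, before any stage runs or output is written
  if (is.null(config$simulate) && is.null(config$inputs$sync)) {
    stop("invalid configuration: either 'simulate' settings or inputs$sync is required")
  }
  if (isTRUE(config$css$enabled) && is.null(config$inputs$blocks) &&
      is.null(config$simulate)) {
    stop("invalid configuration: css stage enabled but no blocks file given")
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, parameters = unclass(config),
                   outputs = list(), counts = list())
  t0 <- Sys.time()
  log_msg <- function(...) {
    message(sprintf("[poolscan %+6.1fs] ", as.numeric(Sys.time() - t0)),
            sprintf(...))
  }
  stage_files <- character(0)
  stage <- function(name, expr) {
    stage_files <<- character(0)
    tryCatch(expr, error = function(e) {
      for (f in stage_files) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(stage_name, label, x) {
    path <- file.path(out_dir, paste0(label, ".tsv"))
    write_tsv(x, path)
    stage_files <<- c(stage_files, path)
    manifest$outputs[[label]] <<- list(stage = stage_name, path = path)
    path
  }

  # ---- data stage -----------------------------------------------------
  # note: stage() evaluates its expression lazily in this frame, so plain
  # assignments below bind in run_pipeline's environment
  sites <- NULL
  panel <- NULL
  blocks <- NULL
  stage("data", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate[setdiff(names(config$simulate), "seed")]
      scfg <- do.call(sim_config, c(sim_args, list(seed = config$seed)))
      truth <- inject_selection(simulate_stock_frequencies(scfg), scfg)
      sim <- simulate_pool_reads(truth, scfg)
      sites <- sim$sites
      panel <- sim$panel
      blocks <- simulate_blocks(scfg)
      log_msg("simulated %d sites x %d pools", n_sites(sites), nrow(panel))
    } else {
      panel <- read_panel(config$inputs$panel)
      sites <- read_sync(config$inputs$sync, panel)
      if (!is.null(config$inputs$blocks)) {
        blocks <- read_blocks_bed(config$inputs$blocks)
      }
      log_msg("read %d sites x %d pools", n_sites(sites), nrow(panel))
    }
  })

  filters <- do.call(filter_config, config$filters[
    c("min_coverage", "min_count", "min_quality", "max_cov_percentile")])
  stocks <- unique(panel$stock)
  tracks <- stock_tracks(sites, panel, merge = config$fst$merge)
  track_caps <- max_coverage_caps(tracks$sites, filters)
  manifest$counts$sites <- n_sites(sites)

  # ---- diversity ------------------------------------------------------
  stage("diversity", {
    div <- do.call(rbind, lapply(stocks, function(s) {
      win <- do.call(rbind, lapply(unique(sites$chrom), function(ch) {
        make_windows(ch, 0L, max(sites$pos[sites$chrom == ch]) + 1L,
                     config$diversity$window_size)
      }))
      ws <- window_stats(tracks$sites, win, filters, pools = s,
                         n_chromosomes = tracks$n_chromosomes[[s]],
                         caps = track_caps)
      cbind(stock = s, ws)
    }))
    emit("diversity", "diversity_windows", div)
    if (!is.null(config$diversity$locus)) {
      loc <- config$diversity$locus
      prof <- do.call(rbind, lapply(stocks, function(s) {
        cbind(stock = s,
              locus_profile(tracks$sites, loc$chrom, loc$start, loc$end,
                            n_windows = config$diversity$n_windows,
                            filters = filters, pools = s,
                            n_chromosomes = tracks$n_chromosomes[[s]],
                            caps = track_caps))
      }))
      emit("diversity", "locus_profile", prof)
    }
  })

  # ---- differentiation ------------------------------------------------
  fst_tables <- NULL
  stage("fst", {
    pairs <- if (identical(config$fst$pairs, "all")) NULL else config$fst$pairs
    fst_tables <- pairwise_scan(sites, panel, pairs = pairs,
                                filters = filters, merge = config$fst$merge)
    summary_rows <- lapply(names(fst_tables), function(nm) {
      t <- fst_tables[[nm]]
      pr <- attr(t, "pair")
      data.frame(stock_a = pr[1], stock_b = pr[2], n_snps = nrow(t),
                 mean_fst = attr(t, "genome_mean"),
                 n_fixed_diff = fixed_differentiation(
                   t, config$fst$fixed_threshold)$count,
                 stringsAsFactors = FALSE)
    })
    emit("fst", "fst_summary", do.call(rbind, summary_rows))
    cmp_stocks <- unique(unlist(lapply(fst_tables, attr, "pair")))
    have_all_pairs <- all(vapply(utils::combn(cmp_stocks, 2, simplify = FALSE),
                                 function(pr) {
                                   paste(pr, collapse = "|") %in% names(fst_tables) ||
                                     paste(rev(pr), collapse = "|") %in% names(fst_tables)
                                 }, logical(1)))
    if (have_all_pairs) {
      for (q in config$fst$top_q) {
        tops <- lapply(fst_tables, top_quantile, q = q)
        specific <- stock_specific_snps(tops, cmp_stocks)
        spec_counts <- data.frame(
          stock = names(specific),
          n_specific = vapply(specific, nrow, integer(1)),
          q = q, stringsAsFactors = FALSE)
        emit("fst", sprintf("stock_specific_q%s",
                            sub("0\\.", "", as.character(q))),
             spec_counts)
      }
    } else {
      log_msg("fst: pair list incomplete, skipping stock-specific SNP tables")
    }
    log_msg("fst: %d pairwise tables", length(fst_tables))
  })

  # ---- structure ------------------------------------------------------
  stage("structure", {
    sres <- structure_scan(sites, panel, filters,
                           min_freq = config$structure$min_freq,
                           k_range = seq(config$structure$k_min,
                                         config$structure$k_max),
                           restarts = config$structure$restarts,
                           n_pcs = config$structure$n_pcs,
                           seed = config$seed)
    emit("structure", "pca_coordinates",
         data.frame(pool = rownames(sres$scores),
                    sres$scores[, seq_len(min(5, ncol(sres$scores)))],
                    stringsAsFactors = FALSE))
    emit("structure", "pca_explained",
         data.frame(pc = seq_along(sres$explained),
                    explained = sres$explained))
    emit("structure", "kmeans_aic", sres$aic)
    emit("structure", "cluster_assignment",
         data.frame(pool = names(sres$assignment),
                    cluster = as.integer(sres$assignment),
                    chosen_k = sres$k, stringsAsFactors = FALSE))
    manifest$counts$chosen_k <- sres$k
    log_msg("structure: %d informative SNPs, chosen k = %d", sres$n_snps, sres$k)
  })

  # ---- css ------------------------------------------------------------
  if (isTRUE(config$css$enabled)) {
    stage("css", {
      cmp <- config$css$comparisons
      if (is.null(cmp)) {
        cmp <- names(fst_tables)  # default: every scanned pair
      }
      missing_cmp <- setdiff(cmp, names(fst_tables))
      if (length(missing_cmp)) {
        stop("comparisons not in the FST scan: ",
             paste(missing_cmp, collapse = ", "))
      }
      css <- css_score(fst_tables[cmp])
      outliers <- top_css(css, q = config$css$top_q)
      emit("css", "css_scores", css)
      emit("css", "css_outliers", outliers)
      if (!is.null(blocks)) {
        enriched <- map_to_blocks(outliers, css, blocks,
                                  min_snps_exclusive = config$css$min_block_snps)
        emit("css", "enriched_blocks", enriched[enriched$reported, , drop = FALSE])
      }
      manifest$counts$css_outliers <- nrow(outliers)
      log_msg("css: %d SNPs scored, %d outliers", nrow(css), nrow(outliers))
    })
  }

  for (label in names(manifest$outputs)) {
    manifest$outputs[[label]]$md5 <-
      unname(tools::md5sum(manifest$outputs[[label]]$path))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  log_msg("wrote %d outputs + manifest", length(manifest$outputs))
  invisible(manifest)
}
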
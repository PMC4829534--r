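#' Run the full turnover analysis pipeline
#'
#' Drives the whole analysis on one dataset: common-genome masking,
#' depth normalization, binarization at the configured thresholds, sharing
#' classes, the bootstrapped sharing tree, taxa- and depth-rarefaction with
#' saturation fits, run-length analysis and (when annotation features are
#' configured) shuffle enrichment. All artifacts are written under the
#' output directory as TSV/BED/Newick/JSON and an append-only manifest
#' records every stage with input/output checksums, seeds and warnings, so
#' a rerun with identical config reproduces identical checksums.
#'
#' @param config Path to a YAML file or an equivalent named list. Recognized
#'   entries: `counts` / `genomic` (TSV paths from [write_count_matrix()])
#'   or `simulate` (list of [turnover_model()] arguments plus `seed` and
#'   optional `dropout`); `required_taxa`; `min_count`; `target_total`;
#'   `thresholds` (default 1, 10, 100); `n_boot`; `n_orders`; `n_draws`;
#'   `n_shuffles`; `fdr`; `features` (named list of BED paths);
#'   `seeds` (named per-stage: `normalize`, `tree`, `rarefaction`,
#'   `enrichment`); `out_dir`.
#' @return A `run_manifest` (list of stage records), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in c(config$counts, config$genomic, unlist(config$features)))
    if (!file.exists(p)) stop("input path missing: ", p, call. = FALSE)

  seeds <- config$seeds %||% list()
  thresholds <- unlist(config$thresholds %||% c(1, 10, 100))
  manifest <- list()
  t0 <- Sys.time()
  record <- function(stage, outputs, warnings = character(0), info = list()) {
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, outputs = outputs,
      checksums = as.list(tools::md5sum(outputs)),
      warnings = warnings, info = info)
  }
  collect <- function(expr) {
    w <- character(0)
    val <- withCallingHandlers(expr, warning = function(cnd) {
      w <<- c(w, conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
    list(value = val, warnings = w)
  }

  # -- inputs ----------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_seed <- sim_args$seed %||% 1L
    dropout <- sim_args$dropout %||% 0
    sim_args$seed <- NULL
    sim_args$dropout <- NULL
    model <- do.call(turnover_model, sim_args)
    ds <- simulate_dataset(model, seed = sim_seed, dropout = dropout)
    counts <- ds$counts
    genomic <- ds$genomic
    truth_tree <- file.path(out_dir, "truth_tree.nwk")
    write_newick(ds$truth$tree, truth_tree)
    record("simulate", truth_tree,
           info = list(seed = sim_seed, n_windows = model$n_windows))
  } else {
    counts <- read_count_matrix(config$counts)
    genomic <- if (!is.null(config$genomic)) read_count_matrix(config$genomic)
    ds <- NULL
  }
  windows <- counts$windows
  taxa <- unique(counts$samples$taxon)

  # -- stage 1: common-genome mask ------------------------------------------
  req <- config$required_taxa %||% (if (!is.null(genomic))
    colnames(taxon_counts(genomic)) else character(0))
  mask <- if (!is.null(genomic))
    common_genome_mask(genomic, req, min_count = config$min_count %||% 1L)
  else common_genome_mask(matrix(1, nrow(counts$counts), 0,
                                 dimnames = list(rownames(counts$counts), NULL)),
                          character(0))
  mask_path <- file.path(out_dir, "common_genome_mask.bed")
  write_bed(data.frame(windows[, c("chrom", "start", "end")],
                       name = as.integer(mask)), mask_path)
  record("mask", mask_path, info = list(n_masked = sum(mask),
                                        required_taxa = req))

  # -- stage 2: depth normalization -----------------------------------------
  tgt <- config$target_total %||% min(colSums(counts$counts))
  norm <- normalize_by_subsampling(counts, tgt, seed = seeds$normalize %||% 1L)
  norm_path <- file.path(out_dir, "counts_normalized.tsv")
  write_count_matrix(norm, norm_path)
  record("normalize", c(norm_path, paste0(norm_path, ".json")),
         info = list(target_total = tgt, seed = seeds$normalize %||% 1L))

  # -- stage 3: binarize at all thresholds ----------------------------------
  pres <- lapply(thresholds, function(tau) binarize(norm, tau = tau, mask = mask))
  names(pres) <- paste0("tau", thresholds)
  cov <- lapply(pres, coverage_fraction)
  cov_df <- data.frame(tau = rep(thresholds, each = length(taxa) + 1),
                       taxon = rep(c(names(cov[[1]]$per_taxon), "union"),
                                   length(thresholds)),
                       coverage = unlist(lapply(cov, function(cc)
                         c(cc$per_taxon, cc$union))))
  cov_path <- file.path(out_dir, "coverage_fractions.tsv")
  utils::write.table(cov_df, cov_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("binarize", cov_path, info = list(thresholds = thresholds))

  # -- stage 4: sharing classes ---------------------------------------------
  tc <- taxon_counts(norm)[as.logical(mask), , drop = FALSE]
  sharing <- classify_sharing(pres[[1]], counts = tc, thresholds = thresholds)
  shr_path <- file.path(out_dir, "sharing_classes.tsv")
  utils::write.table(sharing$per_window, shr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("sharing", shr_path,
         info = list(class_counts = as.list(sharing$class_counts)))

  # -- stage 5: sharing tree with bootstrap supports ------------------------
  res5 <- collect(bootstrap_supports(pres[[1]],
                                     n_boot = config$n_boot %||% 100L,
                                     seed = seeds$tree %||% 1L))
  tree <- res5$value
  tree_path <- file.path(out_dir, "sharing_tree.nwk")
  write_newick(tree, tree_path)
  record("tree", tree_path, warnings = res5$warnings,
         info = list(n_boot = config$n_boot %||% 100L,
                     n_clamped = attr(tree, "n_clamped"),
                     low_support = as.list(attr(tree, "low_support"))))

  # -- stage 6: rarefaction and saturation fits -----------------------------
  rt <- rarefy_taxa(pres[[1]], n_orders = config$n_orders %||% 100L,
                    seed = seeds$rarefaction %||% 1L)
  rd <- rarefy_depth(norm, mask = mask, n_draws = config$n_draws %||% 5L,
                     seed = (seeds$rarefaction %||% 1L) + 1L)
  ft <- fit_saturation(rt)
  fd <- fit_saturation(rd)
  paths6 <- file.path(out_dir, c("rarefaction_taxa.tsv", "rarefaction_depth.tsv",
                                 "fit_taxa.json", "fit_depth.json"))
  write_curve(rt, paths6[1]); write_curve(rd, paths6[2])
  write_fit(ft, paths6[3]); write_fit(fd, paths6[4])
  record("rarefaction", paths6,
         info = list(taxa_winner = ft$winner, depth_winner = fd$winner))

  # -- stage 7: run lengths --------------------------------------------------
  union_pres <- rowSums(pres[[1]]) > 0
  rl <- run_lengths(union_pres, windows, mask = mask)
  rl_path <- file.path(out_dir, "run_lengths.tsv")
  utils::write.table(as.data.frame(rl), rl_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("regions", rl_path,
         info = list(max_length_bp = attr(rl, "summary")$max_length_bp))

  # -- stage 8: enrichment (needs features) ----------------------------------
  feats <- NULL
  if (!is.null(config$features)) {
    feats <- lapply(config$features, read_bed)
  } else if (!is.null(ds)) {
    # synthetic annotation: the conserved core labelled as core exons
    core_idx <- which(ds$truth$core)
    feats <- list(core_exons = windows[core_idx, c("chrom", "start", "end")])
  }
  if (!is.null(feats) && sum(mask) > 0) {
    midx <- as.logical(mask)
    n_tx <- rowSums(pres[[1]])
    masked_win <- windows[midx, , drop = FALSE]
    tg <- list(
      single = masked_win[n_tx == 1, c("chrom", "start", "end")],
      all = masked_win[n_tx == ncol(pres[[1]]), c("chrom", "start", "end")],
      any = masked_win[n_tx >= 1, c("chrom", "start", "end")])
    tg <- tg[vapply(tg, nrow, 1L) > 0]
    chrom_sizes <- attr(windows, "chrom_sizes")
    res8 <- collect(shuffle_enrichment(
      feats, tg, chrom_sizes, n_shuffles = config$n_shuffles %||% 200L,
      seed = seeds$enrichment %||% 1L,
      within = masked_win[, c("chrom", "start", "end")],
      fdr = config$fdr %||% 0.05))
    enr_path <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(as.data.frame(res8$value), enr_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("enrichment", enr_path, warnings = res8$warnings,
           info = list(n_shuffles = config$n_shuffles %||% 200L))
  }

  manifest_obj <- list(created = format(t0, "%Y-%m-%d %H:%M:%S"),
                       stages = manifest)
  jsonlite::write_json(manifest_obj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  structure(manifest_obj, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline manifest:", length(x$stages), "stages completed\n")
  for (s in x$stages) {
    nw <- length(s$warnings)
    cat(sprintf("  %-12s %d output(s)%s\n", s$stage, length(s$outputs),
                if (nw) paste0("  [", nw, " warning(s)]") else ""))
  }
  invisible(x)
}
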
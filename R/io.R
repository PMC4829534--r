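#' Read a BED-style interval file
#'
#' Reads BED3/BED4 (tab-separated, 0-based half-open, no header). Column 4,
#' when present, is returned as `name` (used for fragment sample ids and
#' window indices). Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @return Data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("BED line(s) with fewer than 3 fields: line ",
         paste(utils::head(which(nf < 3), 5), collapse = ", "), call. = FALSE)
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop("malformed BED interval at line ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (need numeric 0 <= start < end)", call. = FALSE)
  out <- data.frame(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(parts, `[[`, character(1), 4)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Write intervals as BED
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optional
#'   `name` column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a count matrix as TSV with a JSON metadata sidecar
#'
#' The TSV holds windows as rows (first column `window`) and samples as
#' columns; `<path>.json` records the sample metadata, dropped-fragment
#' tallies and window grid provenance.
#'
#' @param counts A `count_matrix`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(window = rownames(counts$counts), counts$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(samples = counts$samples,
               dropped = as.list(counts$dropped),
               n_input = as.list(counts$n_input),
               window_size = attr(counts$windows, "window_size"),
               chrom_sizes = as.list(attr(counts$windows, "chrom_sizes")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$window
  meta_path <- paste0(path, ".json")
  samples <- NULL
  wins <- NULL
  dropped <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    samples <- as.data.frame(meta$samples)
    dropped <- unlist(meta$dropped)
    wins <- make_windows(unlist(meta$chrom_sizes), meta$window_size)
  }
  if (is.null(wins)) {
    wins <- make_windows(c(unknown = nrow(m) * 200), 200)
  }
  count_matrix(m, wins, samples = samples, dropped = dropped)
}

#' Write / read trees in Newick format
#'
#' Thin validated wrappers over `ape::write.tree()` / `ape::read.tree()`
#' preserving branch lengths (12 significant digits) and node support
#' labels, so that a write/read cycle is an identity on topology, lengths
#' and supports.
#'
#' @param tree An `ape::phylo`.
#' @param path File path.
#' @return `write_newick` the path invisibly; `read_newick` the tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  tree
}

#' Write a rarefaction curve as TSV
#'
#' @param curve A `rarefaction_curve`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a saturation fit as JSON
#'
#' @param fit A `saturation_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  co <- coef(fit)
  jsonlite::write_json(list(
    winner = fit$winner, converged = fit$converged,
    bic = as.list(fit$bic), delta_bic = fit$delta_bic,
    bayes_factor = fit$bayes_factor, support = fit$support,
    asymptote = fit$asymptote,
    asymptote_plausible = fit$asymptote_plausible,
    predicted_at_2x = fit$predicted_at_2x, x2 = fit$x2,
    coef = lapply(co, as.list), axis = fit$axis, note = fit$note),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
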
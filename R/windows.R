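#' Tile a genome into fixed non-overlapping windows
#'
#' Builds the fixed window grid used throughout the package: non-overlapping
#' windows of `window_size` bp (default 200) tiling each chromosome from
#' position 0. Trailing partial windows (chromosome ends shorter than
#' `window_size`) are dropped so that every window has identical length and
#' coverage fractions share a uniform denominator.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param window_size Window length in bp; a single positive integer.
#'
#' @return A `genome_windows` data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `index` (contiguous from 0, ordered by
#'   chromosome name then start). The window size is kept as an attribute.
#' @examples
#' make_windows(c(chr1 = 1000), 200)
#' @export
make_windows <- function(chrom_sizes, window_size = 200L) {
  if (length(window_size) != 1L || !is.finite(window_size) || window_size < 1)
    stop("`window_size` must be a single positive integer", call. = FALSE)
  window_size <- as.integer(window_size)
  if (length(chrom_sizes) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), index = integer())
  } else {
    if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)))
      stop("`chrom_sizes` must be a named vector", call. = FALSE)
    if (any(chrom_sizes < 0)) stop("chromosome lengths must be >= 0", call. = FALSE)
    chrom_sizes <- chrom_sizes[order(names(chrom_sizes))]
    n_win <- floor(chrom_sizes / window_size)
    chrom <- rep(names(chrom_sizes), n_win)
    start <- unlist(lapply(n_win, function(k) {
      if (k == 0) integer(0) else (seq_len(k) - 1L) * window_size
    }), use.names = FALSE)
    if (is.null(start)) start <- integer(0)
    out <- data.frame(chrom = chrom, start = start, end = start + window_size,
                      index = seq_along(start) - 1L)
  }
  attr(out, "window_size") <- window_size
  attr(out, "chrom_sizes") <- chrom_sizes
  class(out) <- c("genome_windows", "data.frame")
  out
}

#' Construct a count matrix container
#'
#' Low-level constructor bundling a windows-by-samples count matrix with its
#' window grid and per-sample metadata. Usually produced by
#' [count_fragments()] or the simulator rather than called directly.
#'
#' @param counts Non-negative integer matrix, windows in rows (rownames are
#'   window indices), samples in columns.
#' @param windows The `genome_windows` grid the rows refer to.
#' @param samples Optional data.frame with columns `sample_id`, `taxon`,
#'   `tissue`, `replicate`; defaults to one taxon per column name.
#' @param dropped Named integer vector: fragments per sample that fell
#'   outside the grid.
#' @param n_input Named integer vector: input fragments per sample.
#' @return A `count_matrix` object (list with elements `counts`, `windows`,
#'   `samples`, `dropped`, `n_input`).
#' @export
count_matrix <- function(counts, windows, samples = NULL, dropped = NULL,
                         n_input = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts),
                          taxon = colnames(counts),
                          tissue = NA_character_, replicate = 1L)
  }
  stopifnot(nrow(samples) == ncol(counts))
  if (is.null(dropped)) dropped <- stats::setNames(integer(ncol(counts)), colnames(counts))
  if (is.null(n_input)) n_input <- colSums(counts) + dropped
  structure(list(counts = counts, windows = windows, samples = samples,
                 dropped = dropped, n_input = n_input),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Window count matrix:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples\n")
  cat("  taxa:", paste(unique(x$samples$taxon), collapse = ", "), "\n")
  cat("  fragments per sample:",
      paste(range(colSums(x$counts)), collapse = " - "), "\n")
  if (any(x$dropped > 0))
    cat("  dropped fragments (outside grid):", sum(x$dropped), "\n")
  invisible(x)
}

#' Count aligned fragments per genome window
#'
#' Assigns each fragment to the single window holding the strict majority of
#' its span, operationalized as the window containing the fragment midpoint
#' (`floor((start + end) / 2)`). Paired reads are expected to arrive as one
#' fragment interval and are therefore counted once. Fragments whose midpoint
#' falls outside the grid (unknown chromosome or beyond the last full window)
#' are dropped and tallied per sample.
#'
#' @param fragments Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `sample_id`.
#' @param windows A `genome_windows` grid from [make_windows()].
#' @param samples Optional sample metadata (see [count_matrix()]).
#' @return A `count_matrix`; column sums plus the per-sample dropped tally
#'   equal the number of input fragments per sample.
#' @export
count_fragments <- function(fragments, windows, samples = NULL) {
  stopifnot(inherits(windows, "genome_windows"))
  need <- c("chrom", "start", "end", "sample_id")
  if (!all(need %in% names(fragments)))
    stop("`fragments` needs columns chrom, start, end, sample_id", call. = FALSE)
  bad <- which(fragments$start >= fragments$end)
  if (length(bad))
    stop("malformed fragment interval (start >= end) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  ws <- attr(windows, "window_size")
  sample_ids <- if (!is.null(samples)) samples$sample_id else
    sort(unique(as.character(fragments$sample_id)))
  n_win <- nrow(windows)

  # per-chromosome offset of the first window index and number of windows
  ch <- unique(windows$chrom)
  off <- stats::setNames(vapply(ch, function(cc) min(windows$index[windows$chrom == cc]),
                                numeric(1)), ch)
  nwc <- stats::setNames(vapply(ch, function(cc) sum(windows$chrom == cc),
                                numeric(1)), ch)

  mid <- (fragments$start + fragments$end) %/% 2
  frag_ch <- as.character(fragments$chrom)
  widx <- rep(NA_real_, nrow(fragments))
  known <- frag_ch %in% ch
  wi <- mid[known] %/% ws
  ok <- wi < nwc[frag_ch[known]] & mid[known] >= 0
  widx[known][ok] <- off[frag_ch[known]][ok] + wi[ok]

  sid <- factor(as.character(fragments$sample_id), levels = sample_ids)
  counts <- matrix(0L, nrow = n_win, ncol = length(sample_ids),
                   dimnames = list(windows$index, sample_ids))
  keep <- !is.na(widx)
  if (any(keep)) {
    tab <- table(factor(widx[keep], levels = windows$index), sid[keep])
    counts[] <- as.integer(tab)
  }
  dropped <- as.integer(table(sid[!keep]))
  names(dropped) <- sample_ids
  n_input <- as.integer(table(sid))
  names(n_input) <- sample_ids
  count_matrix(counts, windows, samples = samples, dropped = dropped,
               n_input = n_input)
}

#' Aggregate sample columns of a count matrix to per-taxon totals
#'
#' Sums the counts of all samples (tissues, replicates) belonging to the
#' same taxon.
#'
#' @param counts A `count_matrix`.
#' @return Windows-by-taxa numeric matrix.
#' @export
taxon_counts <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tx <- as.character(counts$samples$taxon)
  taxa <- unique(tx)
  out <- vapply(taxa, function(t) {
    rowSums(counts$counts[, tx == t, drop = FALSE])
  }, numeric(nrow(counts$counts)))
  rownames(out) <- rownames(counts$counts)
  out
}

#' Common-genome mask from genomic coverage
#'
#' A window belongs to the common genome if its genomic fragment count
#' reaches `min_count` in every required taxon — the shared analysis space in
#' which presence/absence of transcription can be compared without mapping
#' bias between diverged genomes.
#'
#' @param genomic_counts A `count_matrix` of genomic (DNA) fragment counts,
#'   or a plain windows-by-taxa matrix.
#' @param required_taxa Character vector of taxa that must all be covered.
#'   An empty set yields the vacuous all-`TRUE` mask.
#' @param min_count Minimum genomic fragment count per taxon (default 1).
#' @return Logical vector over windows of class `common_genome_mask`, with
#'   the taxon set and threshold recorded as attributes.
#' @export
common_genome_mask <- function(genomic_counts, required_taxa, min_count = 1L) {
  m <- if (inherits(genomic_counts, "count_matrix")) taxon_counts(genomic_counts)
       else as.matrix(genomic_counts)
  required_taxa <- as.character(required_taxa)
  missing_tx <- setdiff(required_taxa, colnames(m))
  if (length(missing_tx))
    stop("required taxa absent from genomic counts: ",
         paste(missing_tx, collapse = ", "), call. = FALSE)
  if (length(required_taxa) == 0L) {
    mask <- rep(TRUE, nrow(m))
  } else {
    mask <- rowSums(m[, required_taxa, drop = FALSE] >= min_count) ==
      length(required_taxa)
  }
  names(mask) <- rownames(m)
  structure(mask, taxa = required_taxa, min_count = min_count,
            class = c("common_genome_mask", "logical"))
}

#' Normalize samples to equal depth by subsampling fragments
#'
#' Draws, for each sample column, exactly `target_total` fragments without
#' replacement from the observed per-window counts (a multivariate
#' hypergeometric draw), mirroring per-file read subsampling of alignment
#' files. Column sums of the result equal the target exactly and no window
#' count can grow.
#'
#' @param counts A `count_matrix`.
#' @param target_total Single target, or named vector (by sample id).
#' @param seed Optional RNG seed; the caller's RNG state is untouched.
#' @return A `count_matrix` with equalized column sums.
#' @export
normalize_by_subsampling <- function(counts, target_total, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  cs <- colSums(counts$counts)
  tgt <- if (length(target_total) == 1L && is.null(names(target_total)))
    stats::setNames(rep(target_total, ncol(counts$counts)), colnames(counts$counts))
  else target_total[colnames(counts$counts)]
  if (anyNA(tgt)) stop("target_total missing for some samples", call. = FALSE)
  over <- names(cs)[tgt > cs]
  if (length(over))
    stop("subsampling target exceeds available fragments for sample(s): ",
         paste(over, collapse = ", "), call. = FALSE)
  new <- counts
  with_local_seed(seed, {
    for (j in seq_len(ncol(counts$counts))) {
      new$counts[, j] <- rmvhyper(counts$counts[, j], as.integer(tgt[j]))
    }
  })
  new$n_input <- stats::setNames(as.integer(tgt), colnames(counts$counts))
  new$dropped <- stats::setNames(integer(ncol(counts$counts)), colnames(counts$counts))
  new
}
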
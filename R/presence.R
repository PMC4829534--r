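#' Binarize window counts into a presence/absence matrix
#'
#' Thresholds fragment counts at `tau` reads ("at least tau") and restricts
#' to the common-genome mask. By default sample columns are first aggregated
#' per taxon (tissues and replicates summed) and thresholded afterwards; set
#' `by = "sample"` to threshold each sample column separately.
#'
#' @param counts A `count_matrix`.
#' @param tau Read threshold (>= 1); presence means count >= tau.
#' @param mask Optional `common_genome_mask`; default keeps all windows.
#' @param by Aggregate to `"taxon"` (default) or keep per `"sample"`.
#' @return Integer 0/1 matrix (masked windows x taxa) of class
#'   `presence_matrix`, with `tau`, `by` and the number of masked windows as
#'   attributes. Row names are window indices.
#' @export
binarize <- function(counts, tau = 1L, mask = NULL, by = c("taxon", "sample")) {
  by <- match.arg(by)
  if (length(tau) != 1L || !is.finite(tau) || tau < 1)
    stop("`tau` must be a single threshold >= 1", call. = FALSE)
  m <- if (inherits(counts, "count_matrix")) {
    if (by == "taxon") taxon_counts(counts) else counts$counts
  } else as.matrix(counts)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(m))
    m <- m[as.logical(mask), , drop = FALSE]
  }
  p <- (m >= tau) * 1L
  structure(p, tau = tau, by = by, n_masked = nrow(p),
            class = c("presence_matrix", class(p)))
}

#' Coverage fraction per taxon and for the union
#'
#' The fraction of common-genome windows showing transcription, per taxon
#' and for the union across all taxa.
#'
#' @param presence A `presence_matrix`.
#' @return List with `per_taxon` (named fractions) and `union` (scalar).
#' @export
coverage_fraction <- function(presence) {
  if (nrow(presence) == 0L)
    stop("empty mask: no windows to compute coverage over", call. = FALSE)
  list(per_taxon = colMeans(presence),
       union = mean(rowSums(presence) > 0))
}

#' Classify transcribed windows into sharing classes
#'
#' Windows present in at least one taxon are classified by how many taxa
#' show them: `single` (exactly 1), `intermediate` (2 to T-1) or `all`
#' (every taxon). Classes are assigned on the tau = 1 presence matrix,
#' independent of coverage; when `counts` are supplied each taxon's windows
#' are then cross-tabulated by the highest coverage threshold they reach.
#'
#' @param presence A `presence_matrix` at tau = 1 with at least 2 taxa.
#' @param counts Optional per-taxon count matrix (same rows as `presence`,
#'   e.g. from a masked [taxon_counts()]) for the coverage breakdown.
#' @param thresholds Coverage thresholds for the breakdown (default 1, 10, 100).
#' @return A `sharing_profile`: per-window data.frame (`index`, `n_taxa`,
#'   `class`), class counts, and optionally a per-taxon class-by-coverage
#'   table.
#' @export
classify_sharing <- function(presence, counts = NULL,
                             thresholds = c(1L, 10L, 100L)) {
  if (ncol(presence) < 2L)
    stop("sharing classes need at least 2 taxa", call. = FALSE)
  n_taxa <- rowSums(presence)
  transcribed <- n_taxa >= 1
  cls <- rep(NA_character_, nrow(presence))
  cls[n_taxa == 1] <- "single"
  cls[n_taxa >= 2 & n_taxa < ncol(presence)] <- "intermediate"
  cls[n_taxa == ncol(presence)] <- "all"
  per_window <- data.frame(
    index = rownames(presence) %||% as.character(seq_len(nrow(presence)) - 1L),
    n_taxa = n_taxa, class = cls, stringsAsFactors = FALSE)
  class_counts <- table(factor(cls[transcribed],
                               levels = c("single", "intermediate", "all")))
  by_taxon <- NULL
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == nrow(presence))
    thresholds <- sort(thresholds)
    rows <- list()
    for (tx in colnames(presence)) {
      pres_tx <- presence[, tx] == 1 & transcribed
      if (!any(pres_tx)) next
      lev <- pmax(findInterval(counts[pres_tx, tx], thresholds), 1L)
      tab <- table(class = factor(cls[pres_tx],
                                  levels = c("single", "intermediate", "all")),
                   coverage = factor(paste0(">=", thresholds[lev]),
                                     levels = paste0(">=", thresholds)))
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      df$taxon <- tx
      rows[[tx]] <- df
    }
    by_taxon <- do.call(rbind, rows)
    rownames(by_taxon) <- NULL
  }
  structure(list(per_window = per_window, class_counts = class_counts,
                 by_taxon = by_taxon, n_taxa_total = ncol(presence)),
            class = "sharing_profile")
}

#' @export
print.sharing_profile <- function(x, ...) {
  n <- sum(x$class_counts)
  cat("Sharing profile over", nrow(x$per_window), "windows (",
      n, "transcribed in >= 1 of", x$n_taxa_total, "taxa)\n")
  pc <- round(100 * x$class_counts / max(1, n), 1)
  for (k in names(x$class_counts))
    cat(sprintf("  %-12s %8d  (%.1f%%)\n", k, x$class_counts[[k]], pc[[k]]))
  invisible(x)
}

#' Taxon-specific highly expressed windows
#'
#' Windows whose fragment count exceeds `min_reads` (strictly) in exactly
#' one taxon while every other taxon shows no read at all — candidate
#' lineage-specific high-expression transcripts.
#'
#' @param counts A `count_matrix` or per-taxon count matrix.
#' @param mask Optional `common_genome_mask`.
#' @param min_reads Strict lower bound on the focal taxon's count (default 50).
#' @return Data.frame with columns `taxon`, `index`, `count`.
#' @export
taxon_specific_high_expression <- function(counts, mask = NULL, min_reads = 50L) {
  if (min_reads < 1) stop("`min_reads` must be >= 1", call. = FALSE)
  m <- if (inherits(counts, "count_matrix")) taxon_counts(counts) else as.matrix(counts)
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  n_present <- rowSums(m >= 1)
  hi <- m > min_reads
  hit <- which(rowSums(hi) == 1 & n_present == 1)
  if (!length(hit))
    return(data.frame(taxon = character(), index = character(), count = numeric()))
  tx <- colnames(m)[max.col(hi[hit, , drop = FALSE], ties.method = "first")]
  idx <- rownames(m)[hit] %||% as.character(hit - 1L)
  out <- data.frame(taxon = tx, index = idx,
                    count = m[cbind(hit, match(tx, colnames(m)))])
  out[order(out$taxon, out$index), , drop = FALSE]
}

#' Singleton windows and their re-detection across the dataset
#'
#' For every window supported by exactly one fragment (a singleton) in a
#' focal sample, checks whether any other sample detects the window at all,
#' and whether re-detection happens in another tissue or another taxon.
#' Windows never re-detected anywhere are dataset-wide unique.
#'
#' @param counts A `count_matrix` with at least 2 sample columns (per-sample
#'   counts, not taxon-aggregated).
#' @return A `singleton_report`: per-sample data.frame with singleton counts
#'   and the fractions re-detected (overall, other tissue, other taxon) and
#'   dataset-wide unique. Fractions of singletons; `frac_windows` is
#'   singletons over all windows.
#' @export
singleton_redetection <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  meta <- counts$samples
  det <- m >= 1
  rows <- lapply(seq_len(ncol(m)), function(j) {
    s <- m[, j] == 1
    n_s <- sum(s)
    others <- det[, -j, drop = FALSE]
    any_other <- rowSums(others) > 0
    other_tissue <- if (all(is.na(meta$tissue))) rep(NA, nrow(m)) else
      rowSums(det[, -j, drop = FALSE][, meta$tissue[-j] != meta$tissue[j],
                                      drop = FALSE]) > 0
    other_taxon <- rowSums(det[, -j, drop = FALSE][, meta$taxon[-j] != meta$taxon[j],
                                                   drop = FALSE]) > 0
    data.frame(
      sample_id = colnames(m)[j],
      n_singletons = n_s,
      frac_windows = n_s / nrow(m),
      frac_redetected = if (n_s) mean(any_other[s]) else 0,
      frac_other_tissue = if (n_s) mean(other_tissue[s]) else 0,
      frac_other_taxon = if (n_s) mean(other_taxon[s]) else 0,
      frac_unique = if (n_s) mean(!any_other[s]) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(per_sample = out), class = "singleton_report")
}

#' @export
print.singleton_report <- function(x, ...) {
  cat("Singleton re-detection report (", nrow(x$per_sample), "samples )\n")
  print(x$per_sample, digits = 3)
  invisible(x)
}

#' Probability of missing a transcribed window by sampling alone
#'
#' Under Poisson fragment sampling, a window truly expressed at a mean of
#' `lambda` fragments per sample is missed (zero fragments) in `k`
#' independent samples with probability `exp(-lambda * k)`. At one expected
#' fragment this is e^-1, about 37%, in a single sample, and about 0.01%
#' across nine samples — the reason a singleton absent from one taxon is
#' still very unlikely to be absent from all others if truly shared.
#'
#' @param lambda Expected fragments per window per sample (>= 0); vectorized.
#' @param k Number of independent samples (>= 1).
#' @return Miss probability `exp(-lambda * k)`.
#' @examples
#' detection_miss_probability(1, 1)   # ~0.37
#' detection_miss_probability(1, 9)   # ~1.2e-4
#' @export
detection_miss_probability <- function(lambda, k = 1) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  if (any(k < 1)) stop("`k` must be >= 1", call. = FALSE)
  exp(-lambda * k)
}
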
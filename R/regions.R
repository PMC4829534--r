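#' Run lengths of transcribed and non-transcribed stretches
#'
#' Segments the masked window grid into maximal runs of identical state
#' (transcribed / non-transcribed, from the any-taxon union presence). Runs
#' are broken at chromosome boundaries and at common-genome mask gaps, so
#' within each contiguous masked block run lengths alternate in state and
#' sum exactly to the block span. Lengths are reported in bp (multiples of
#' the window size).
#'
#' @param union_presence Logical/0-1 vector: one entry per masked window (in
#'   mask order) or per grid window.
#' @param windows The `genome_windows` grid.
#' @param mask Optional `common_genome_mask`; default all windows.
#' @return A `run_length_distribution` data.frame with columns `chrom`,
#'   `start`, `end`, `state`, `n_windows`, `length_bp`, plus a `summary`
#'   attribute with the maximum run length per state.
#' @export
run_lengths <- function(union_presence, windows, mask = NULL) {
  stopifnot(inherits(windows, "genome_windows"))
  ws <- attr(windows, "window_size")
  if (is.null(mask)) mask <- rep(TRUE, nrow(windows))
  mask <- as.logical(mask)
  stopifnot(length(mask) == nrow(windows))
  w <- windows[mask, , drop = FALSE]
  p <- as.integer(union_presence != 0)
  if (length(p) == nrow(windows)) p <- p[mask]
  stopifnot(length(p) == nrow(w))
  if (nrow(w) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      state = character(), n_windows = integer(),
                      length_bp = integer())
  } else {
    # contiguous masked blocks: same chromosome and consecutive indices
    new_block <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                     diff(w$index) != 1L)
    block <- cumsum(new_block)
    rows <- lapply(split(seq_len(nrow(w)), block), function(ii) {
      r <- rle(p[ii])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      data.frame(chrom = w$chrom[ii[1]],
                 start = w$start[ii[starts]],
                 end = w$end[ii[ends]],
                 state = ifelse(r$values == 1, "transcribed", "non-transcribed"),
                 n_windows = r$lengths,
                 length_bp = r$lengths * ws)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  summ <- vapply(c("transcribed", "non-transcribed"), function(s) {
    l <- out$length_bp[out$state == s]
    if (length(l)) max(l) else 0L
  }, numeric(1))
  structure(out, summary = list(max_length_bp = summ),
            class = c("run_length_distribution", "data.frame"))
}

# Place each feature uniformly at random on its own chromosome (or within
# the allowed blocks of its chromosome), preserving length. `blocks` is a
# merged-interval data.frame or NULL for whole chromosomes.
shuffle_features <- function(features, chrom_sizes, blocks = NULL) {
  len <- features$end - features$start
  if (is.null(blocks)) {
    L <- chrom_sizes[features$chrom]
    if (any(len > L)) stop("feature longer than its chromosome", call. = FALSE)
    start <- floor(stats::runif(nrow(features)) * (L - len + 1))
    return(data.frame(chrom = features$chrom, start = start, end = start + len))
  }
  bl <- split(blocks, blocks$chrom)
  out_start <- numeric(nrow(features))
  for (ch in unique(features$chrom)) {
    ii <- which(features$chrom == ch)
    b <- bl[[ch]]
    if (is.null(b)) stop("no allowed blocks on chromosome ", ch, call. = FALSE)
    bw <- b$end - b$start
    for (i in ii) {
      fits <- bw >= len[i]
      if (!any(fits)) stop("feature of ", len[i], " bp fits no block on ", ch,
                           call. = FALSE)
      wts <- (bw - len[i] + 1) * fits
      k <- sample.int(nrow(b), 1L, prob = wts)
      out_start[i] <- b$start[k] + floor(stats::runif(1) * (bw[k] - len[i] + 1))
    }
  }
  data.frame(chrom = features$chrom, start = out_start, end = out_start + len)
}

#' Permutation test of annotation overlap with transcribed window classes
#'
#' Compares the observed overlap (in bp) between annotation feature sets and
#' target window sets against a null distribution obtained by placing each
#' feature uniformly at random along its own chromosome (length and
#' chromosome preserved, overlaps among shuffled features permitted),
#' optionally restricted to allowed blocks such as the common genome.
#' Two-sided empirical p-values use the add-one correction
#' (`p >= 1 / (n_shuffles + 1)`); Benjamini-Hochberg correction is applied
#' across the whole feature-by-target family.
#'
#' @param features Named list of interval data.frames (`chrom`, `start`,
#'   `end`), or a single data.frame.
#' @param targets Named list of interval data.frames, or a single data.frame.
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param n_shuffles Number of random placements (default 1000).
#' @param seed Optional RNG seed.
#' @param within Optional interval data.frame restricting placements (e.g.
#'   the masked genome as intervals); default whole chromosomes.
#' @param fdr FDR level for the significance flag (default 0.05).
#' @return An `enrichment_result` data.frame: one row per feature-target
#'   pair with `observed`, `expected`, `expected_sd`, `ratio`, `p`, `q`,
#'   `significant`.
#' @export
shuffle_enrichment <- function(features, targets, chrom_sizes,
                               n_shuffles = 1000L, seed = NULL,
                               within = NULL, fdr = 0.05) {
  if (is.data.frame(features)) features <- list(features = features)
  if (is.data.frame(targets)) targets <- list(targets = targets)
  if (n_shuffles < 1) stop("`n_shuffles` must be >= 1", call. = FALSE)
  if (any(vapply(features, nrow, 1L) == 0))
    stop("empty feature set", call. = FALSE)
  if (is.null(names(features))) names(features) <- paste0("F", seq_along(features))
  if (is.null(names(targets))) names(targets) <- paste0("T", seq_along(targets))
  blocks <- if (is.null(within)) NULL else merge_intervals(within)
  tidx <- lapply(targets, overlap_index)

  grid <- expand.grid(feature = names(features), target = names(targets),
                      stringsAsFactors = FALSE)
  obs <- mapply(function(f, t) overlap_bp(features[[f]], tidx[[t]]),
                grid$feature, grid$target)
  null <- matrix(NA_real_, n_shuffles, nrow(grid))
  with_local_seed(seed, {
    for (b in seq_len(n_shuffles)) {
      shuf <- lapply(features, shuffle_features, chrom_sizes = chrom_sizes,
                     blocks = blocks)
      null[b, ] <- mapply(function(f, t) overlap_bp(shuf[[f]], tidx[[t]]),
                          grid$feature, grid$target)
    }
  })
  exp_mean <- colMeans(null)
  exp_sd <- apply(null, 2, stats::sd)
  p_hi <- (1 + colSums(null >= rep(obs, each = n_shuffles))) / (n_shuffles + 1)
  p_lo <- (1 + colSums(null <= rep(obs, each = n_shuffles))) / (n_shuffles + 1)
  p <- pmin(1, 2 * pmin(p_hi, p_lo))
  out <- data.frame(feature = grid$feature, target = grid$target,
                    observed = obs, expected = exp_mean, expected_sd = exp_sd,
                    ratio = ifelse(exp_mean > 0, obs / exp_mean, NA_real_),
                    p = p, p_enriched = p_hi, p_depleted = p_lo,
                    q = stats::p.adjust(p, method = "BH"))
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  structure(out, n_shuffles = n_shuffles, fdr = fdr,
            class = c("enrichment_result", "data.frame"))
}

#' Method-bias ratio band from total transcription
#'
#' Shuffling-based enrichment can be biased by the placement scheme itself.
#' Following the control logic of comparing every feature set against the
#' total transcribed space (where most annotations are expected to fall),
#' the spread of observed/expected ratios in that comparison defines a band
#' of ratios that cannot be distinguished from method bias; downstream
#' ratios inside the band are flagged.
#'
#' @param features Named list of feature interval sets.
#' @param total_targets Interval data.frame of the total (any-taxon)
#'   transcribed space.
#' @inheritParams shuffle_enrichment
#' @return List with `lo`, `hi` and the per-feature `ratios`.
#' @export
method_bias_band <- function(features, total_targets, chrom_sizes,
                             n_shuffles = 1000L, seed = NULL, within = NULL) {
  res <- shuffle_enrichment(features, list(total = total_targets),
                            chrom_sizes, n_shuffles = n_shuffles, seed = seed,
                            within = within)
  ratios <- stats::setNames(res$ratio, res$feature)
  list(lo = min(ratios, na.rm = TRUE), hi = max(ratios, na.rm = TRUE),
       ratios = ratios)
}

#' Flag enrichment ratios falling inside the method-bias band
#'
#' @param result An `enrichment_result`.
#' @param band A band from [method_bias_band()].
#' @return The result with an added logical `within_bias_band` column.
#' @export
apply_bias_band <- function(result, band) {
  result$within_bias_band <- !is.na(result$ratio) &
    result$ratio >= band$lo & result$ratio <= band$hi
  result
}
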
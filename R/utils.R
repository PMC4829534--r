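# Internal helpers shared across modules.

# Evaluate `code` with a locally seeded RNG, restoring the caller's RNG state
# afterwards. seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact multivariate hypergeometric draw: subsample `k` items without
# replacement from categories with counts `x`. Two exact routes: direct
# sampling of item ids (vectorized, used for modest totals) or sequential
# conditional hypergeometric draws (O(length(x)) scalar rhyper calls).
rmvhyper <- function(x, k) {
  x <- as.integer(round(x))
  total <- sum(x)
  if (k > total) stop("subsampling target exceeds available items", call. = FALSE)
  if (k == total) return(x)
  if (k == 0L) return(integer(length(x)))
  if (total <= 5e6) {
    ids <- sample.int(total, k)
    idx <- findInterval(ids, cumsum(x), left.open = TRUE) + 1L
    tabulate(idx, nbins = length(x))
  } else {
    out <- integer(length(x))
    rem_total <- total
    rem_k <- k
    for (i in seq_along(x)) {
      if (rem_k == 0L) break
      xi <- x[i]
      rem_total <- rem_total - xi
      d <- stats::rhyper(1L, xi, rem_total, rem_k)
      out[i] <- d
      rem_k <- rem_k - d
    }
    out
  }
}

# Merge possibly overlapping intervals (per chromosome) into disjoint sorted
# blocks. `intervals` is a data.frame with chrom/start/end (0-based half-open).
merge_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  o <- order(intervals$chrom, intervals$start, intervals$end)
  iv <- intervals[o, c("chrom", "start", "end"), drop = FALSE]
  parts <- split(iv, iv$chrom)
  out <- lapply(parts, function(p) {
    s <- p$start; e <- p$end
    keep_s <- numeric(0); keep_e <- numeric(0)
    cs <- s[1]; ce <- e[1]
    if (nrow(p) > 1L) for (i in 2:nrow(p)) {
      if (s[i] <= ce) ce <- max(ce, e[i])
      else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce); cs <- s[i]; ce <- e[i] }
    }
    keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
    data.frame(chrom = p$chrom[1], start = keep_s, end = keep_e)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Build a lookup structure for fast overlap queries against a merged interval
# set: per chromosome the sorted starts/ends and the cumulative covered bp
# strictly before each interval.
overlap_index <- function(intervals) {
  merged <- merge_intervals(intervals)
  parts <- split(merged, merged$chrom)
  lapply(parts, function(p) {
    w <- p$end - p$start
    list(start = p$start, end = p$end, cum = cumsum(c(0, w))[seq_along(w)])
  })
}

# Covered bp in [0, x) for one chromosome's index entry; vectorized over x.
.cov_upto <- function(ix, x) {
  i <- findInterval(x, ix$start)
  out <- numeric(length(x))
  pos <- i > 0L
  ii <- i[pos]
  out[pos] <- ix$cum[ii] + pmax(0, pmin(x[pos], ix$end[ii]) - ix$start[ii])
  out
}

# Total overlap in bp between query intervals and an overlap_index.
overlap_bp <- function(queries, index) {
  if (nrow(queries) == 0L) return(0)
  tot <- 0
  for (ch in unique(queries$chrom)) {
    ix <- index[[ch]]
    if (is.null(ix)) next
    q <- queries[queries$chrom == ch, , drop = FALSE]
    tot <- tot + sum(.cov_upto(ix, q$end) - .cov_upto(ix, q$start))
  }
  tot
}
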
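#' Between-taxon correlation matrix of window coverage
#'
#' Genome-wide association between taxa, either the phi coefficient on
#' binary presence/absence (Pearson correlation specialized to 0/1 data,
#' computed from the 2x2 contingency table of each taxon pair) or Spearman
#' rank correlation on raw counts.
#'
#' A taxon column without variance (all 0 or all 1) leaves phi undefined for
#' its pairs; those entries are recorded as 0 with a warning and flagged, so
#' that downstream distance construction can apply its exclusion rule.
#'
#' @param x Windows-by-taxa matrix: a `presence_matrix` for `method = "phi"`,
#'   counts for `method = "spearman"`.
#' @param method `"phi"` (default) or `"spearman"`.
#' @return Symmetric taxa-by-taxa matrix of class `correlation_matrix`, unit
#'   diagonal, with attributes `method` and `flagged` (logical matrix of
#'   undefined entries).
#' @export
correlation_matrix <- function(x, method = c("phi", "spearman")) {
  method <- match.arg(method)
  m <- unclass(as.matrix(x))
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop("need at least 2 taxa and 2 windows", call. = FALSE)
  t_n <- colnames(m) %||% paste0("T", seq_len(ncol(m)))
  flagged <- matrix(FALSE, ncol(m), ncol(m), dimnames = list(t_n, t_n))
  if (method == "spearman") {
    cc <- stats::cor(m, method = "spearman")
    bad <- apply(m, 2, function(v) length(unique(v)) == 1L)
    if (any(bad)) {
      warning("zero-variance column(s): ", paste(t_n[bad], collapse = ", "),
              "; correlation recorded as 0", call. = FALSE)
      flagged[bad, ] <- TRUE
      flagged[, bad] <- TRUE
      cc[is.na(cc)] <- 0
    }
  } else {
    m <- (m != 0) * 1
    n <- nrow(m)
    n11 <- crossprod(m)
    c1 <- colSums(m)
    n10 <- outer(c1, c1, function(a, b) a) - n11      # i present, j absent
    n01 <- t(n10)
    n00 <- n - n11 - n10 - n01
    denom <- sqrt(outer(c1, c1) * outer(n - c1, n - c1))
    cc <- (n11 * n00 - n10 * n01) / denom
    bad <- c1 == 0 | c1 == n
    if (any(bad)) {
      warning("zero-variance presence column(s): ",
              paste(t_n[bad], collapse = ", "),
              "; phi undefined, recorded as 0", call. = FALSE)
      flagged[bad, ] <- TRUE
      flagged[, bad] <- TRUE
      cc[flagged] <- 0
    }
    diag(cc) <- 1
    dimnames(cc) <- list(t_n, t_n)
  }
  diag(flagged) <- FALSE
  structure(cc, method = method, flagged = flagged,
            class = c("correlation_matrix", "matrix", "array"))
}

#' Manhattan distances between taxa from a correlation matrix
#'
#' `d(i, j) = sum_k |corr(i, k) - corr(j, k)|`: each taxon is represented by
#' its row of correlations with every taxon, and rows are compared by the
#' Manhattan (L1) metric.
#'
#' Entries flagged as undefined in the correlation matrix are skipped for a
#' pair only when flagged in both of the pair's rows; a singly flagged entry
#' still contributes its recorded 0.
#'
#' @param corr A `correlation_matrix`.
#' @return Symmetric non-negative taxa-by-taxa matrix with zero diagonal.
#' @export
manhattan_distances <- function(corr) {
  cc <- unclass(corr)
  flagged <- attr(corr, "flagged")
  if (is.null(flagged) || !any(flagged))
    return(as.matrix(stats::dist(cc, method = "manhattan")))
  n <- nrow(cc)
  d <- matrix(0, n, n, dimnames = dimnames(cc))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- !(flagged[i, ] & flagged[j, ])
    d[i, j] <- d[j, i] <- sum(abs(cc[i, keep] - cc[j, keep]))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with the Studier-Keppler
#' Q-criterion. Deterministic: among joins of minimal Q the pair whose
#' (sorted) smallest member labels are lexicographically smallest is chosen.
#' Negative branch lengths are clamped to 0 after being recorded. Exact on
#' additive distances: given the path-length matrix of a tree with positive
#' branch lengths, the generating topology and lengths are recovered.
#'
#' @param dist Symmetric numeric matrix (or `dist`) with at least 3 taxa;
#'   row/column names are taxon labels.
#' @return An unrooted `ape::phylo` tree. The number of clamped negative
#'   branches is available as `attr(tree, "n_clamped")`.
#' @export
neighbor_joining <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(D))) stop("distances contain NA/NaN/Inf", call. = FALSE)
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  dimnames(D) <- list(labs, labs)

  n_clamped <- 0L
  fmt <- function(x) {
    if (x < 0) n_clamped <<- n_clamped + 1L
    sprintf("%.15g", max(0, x))
  }
  # each active cluster: newick fragment + smallest contained taxon label
  nwk <- labs
  key <- labs
  act <- seq_len(n)

  while (length(act) > 3L) {
    r <- length(act)
    Dm <- D[act, act, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on the pair's smallest member labels
    k1 <- key[act[cand[, 1]]]
    k2 <- key[act[cand[, 2]]]
    a <- pmin(k1, k2); b <- pmax(k1, k2)
    pick <- order(a, b)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    ai <- act[i]; aj <- act[j]
    li <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    new_d <- (D[ai, act] + D[aj, act] - D[ai, aj]) / 2
    # append the new cluster
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, act] <- new_d
    D[act, u] <- new_d
    D[u, u] <- 0
    nwk <- c(nwk, sprintf("(%s:%s,%s:%s)", nwk[ai], fmt(li), nwk[aj], fmt(lj)))
    key <- c(key, min(key[ai], key[aj]))
    act <- c(setdiff(act, c(ai, aj)), u)
  }
  a <- act[1]; b <- act[2]; c <- act[3]
  la <- (D[a, b] + D[a, c] - D[b, c]) / 2
  lb <- (D[a, b] + D[b, c] - D[a, c]) / 2
  lc <- (D[a, c] + D[b, c] - D[a, b]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[a], fmt(la), nwk[b], fmt(lb), nwk[c], fmt(lc))
  tree <- ape::read.tree(text = txt)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

# Canonical bipartition keys of an unrooted tree's internal edges, oriented
# away from the alphabetically first taxon. Returns a character vector.
bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (k in seq_along(pp)) {
    tips <- attr(pp, "labels")[pp[[k]]]
    if (length(tips) %in% c(1L, length(labs))) next  # trivial splits
    if (ref %in% tips) tips <- setdiff(labs, tips)
    if (length(tips) < 2L) next
    out <- c(out, paste(sort(tips), collapse = "|"))
  }
  out
}

#' Sharing tree with bootstrap node supports
#'
#' Builds the point-estimate transcriptome-sharing tree (correlation ->
#' Manhattan distance -> neighbor joining) and attaches bootstrap supports:
#' windows are resampled with replacement `n_boot` times, the full pipeline
#' is rerun on each replicate, and each internal edge of the point tree is
#' annotated with the percentage of replicate trees containing the same
#' bipartition.
#'
#' @param presence A `presence_matrix` (or counts for `method = "spearman"`).
#' @param n_boot Number of bootstrap replicates (>= 1; 1000 for reported trees).
#' @param seed Optional RNG seed.
#' @param method Correlation method, see [correlation_matrix()].
#' @param min_support Nodes below this support (default 70) are listed in
#'   `attr(tree, "low_support")`.
#' @return An `ape::phylo` with `node.label` holding supports in percent
#'   (root label empty).
#' @export
bootstrap_supports <- function(presence, n_boot = 1000L, seed = NULL,
                               method = "phi", min_support = 70) {
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  build <- function(m) {
    cc <- suppressWarnings(correlation_matrix(m, method = method))
    neighbor_joining(manhattan_distances(cc))
  }
  point <- build(presence)
  splits <- bipartitions(point)
  hits <- stats::setNames(numeric(length(splits)), splits)
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(presence), replace = TRUE)
      bt <- build(presence[idx, , drop = FALSE])
      bs <- bipartitions(bt)
      hits[splits %in% bs] <- hits[splits %in% bs] + 1
    }
  })
  support <- 100 * hits / n_boot
  # map supports onto internal nodes of the point tree
  labs <- sort(point$tip.label)
  ref <- labs[1]
  pp <- ape::prop.part(point)
  node_lab <- character(point$Nnode)
  for (k in seq_along(pp)) {
    tips <- attr(pp, "labels")[pp[[k]]]
    if (length(tips) == length(labs)) { node_lab[k] <- ""; next }
    if (ref %in% tips) tips <- setdiff(labs, tips)
    key <- paste(sort(tips), collapse = "|")
    node_lab[k] <- if (key %in% names(support))
      sprintf("%g", support[[key]]) else ""
  }
  point$node.label <- node_lab
  low <- support[support < min_support]
  attr(point, "support") <- support
  attr(point, "low_support") <- low
  point
}

#' Partition terminal branch lengths into sampling-robust and variable parts
#'
#' Builds one sharing tree per replicate presence matrix (independent read
#' subsets of the same samples) and partitions each taxon's terminal branch:
#' the portion shared across replicates — the minimum terminal length — is
#' robust to sampling, the remainder (mean - minimum) reflects sampling
#' variance. The overall sampling-variance percentage is the summed variable
#' component over the summed mean terminal length.
#'
#' @param replicate_presences List (>= 2) of `presence_matrix` objects with
#'   identical taxa.
#' @param method Correlation method passed to [correlation_matrix()].
#' @return A `variance_partition`: per-taxon data.frame (`taxon`, `mean`,
#'   `robust`, `variable`), overall `percent_variable`, the replicate trees
#'   and their majority-rule consensus topology.
#' @export
partition_branch_variance <- function(replicate_presences, method = "phi") {
  if (length(replicate_presences) < 2L)
    stop("need at least 2 replicate sets", call. = FALSE)
  taxa <- colnames(replicate_presences[[1]])
  for (p in replicate_presences)
    if (!identical(sort(colnames(p)), sort(taxa)))
      stop("replicate sets must cover identical taxa", call. = FALSE)
  trees <- lapply(replicate_presences, function(p) {
    cc <- suppressWarnings(correlation_matrix(p, method = method))
    neighbor_joining(manhattan_distances(cc))
  })
  partition_from_trees(trees, taxa)
}

# min/mean partition of terminal branch lengths across replicate trees
partition_from_trees <- function(trees, taxa) {
  term <- vapply(trees, function(tr) {
    tip_edge <- match(seq_along(tr$tip.label), tr$edge[, 2])
    stats::setNames(tr$edge.length[tip_edge], tr$tip.label)[taxa]
  }, numeric(length(taxa)))
  mean_len <- rowMeans(term)
  robust <- apply(term, 1, min)
  variable <- mean_len - robust
  pct <- if (sum(mean_len) > 0) 100 * sum(variable) / sum(mean_len) else 0
  cons <- ape::consensus(trees, p = 0.5)
  structure(list(
    per_taxon = data.frame(taxon = taxa, mean = mean_len, robust = robust,
                           variable = variable, row.names = NULL),
    percent_variable = pct, trees = trees, consensus = cons),
    class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Terminal-branch sampling-variance partition over",
      length(x$trees), "replicate trees\n")
  cat(sprintf("  overall sampling-variance: %.1f%% of terminal branch length\n",
              x$percent_variable))
  print(x$per_taxon, digits = 4)
  invisible(x)
}

#' Split fragments or counts into disjoint random replicate sets
#'
#' Partitions each sample's fragments into `n_sets` disjoint subsets of
#' `set_size` fragments drawn without replacement — the in-silico equivalent
#' of splitting an alignment into independent same-depth sequencing runs.
#' Fragments are the sampling unit, so mate pairs collapsed into single
#' fragment intervals stay together by construction.
#'
#' @param counts A `count_matrix`.
#' @param n_sets Number of disjoint sets (>= 2).
#' @param set_size Fragments per set per sample; default
#'   `floor(min(colSums) / n_sets)`.
#' @param seed Optional RNG seed.
#' @return List of `n_sets` `count_matrix` objects.
#' @export
split_replicates <- function(counts, n_sets, set_size = NULL, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  cs <- colSums(counts$counts)
  if (is.null(set_size)) set_size <- floor(min(cs) / n_sets)
  short <- names(cs)[cs < n_sets * set_size]
  if (length(short))
    stop("insufficient fragments for ", n_sets, " sets of ", set_size,
         " in sample(s): ", paste(short, collapse = ", "), call. = FALSE)
  sets <- lapply(seq_len(n_sets), function(i) counts)
  with_local_seed(seed, {
    for (j in seq_len(ncol(counts$counts))) {
      remaining <- counts$counts[, j]
      for (i in seq_len(n_sets)) {
        drawn <- rmvhyper(remaining, set_size)
        sets[[i]]$counts[, j] <- drawn
        remaining <- remaining - drawn
      }
    }
  })
  for (i in seq_len(n_sets)) {
    sets[[i]]$n_input <- colSums(sets[[i]]$counts)
    sets[[i]]$dropped[] <- 0L
  }
  sets
}
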
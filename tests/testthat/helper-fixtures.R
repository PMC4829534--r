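# Small builders shared across tests.

# presence matrix from a plain 0/1 matrix
as_presence <- function(m, tau = 1L) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m)) - 1L
  structure(m, tau = tau, by = "taxon", n_masked = nrow(m),
            class = c("presence_matrix", class(m)))
}

# count_matrix from a plain matrix with one sample per taxon
as_counts <- function(m, windows = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m)) - 1L
  if (is.null(windows))
    windows <- make_windows(c(chr1 = nrow(m) * 200), 200)
  count_matrix(m, windows)
}

# singleton-only presence (count exactly 1) at taxon level
singleton_presence <- function(cm) {
  tc <- taxon_counts(cm)
  as_presence((tc == 1) * 1L)
}

# random additive distance matrix and its generating tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  list(tree = tr, dist = stats::cophenetic(tr))
}
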
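#' Default ten-taxon mouse phylogeny
#'
#' Ultrametric tree of the ten study taxa — three *M. m. domesticus*
#' populations (DOM_CB, DOM_MC, DOM_AH), two *M. m. musculus* populations
#' (MUS_KH, MUS_VI), *M. m. castaneus* (CAS), *M. spicilegus* (SPI),
#' *M. spretus* (SPR), *M. mattheyi* (MAT) and *Apodemus uralensis* (APO) —
#' with branch lengths in Myr from the published split-time estimates
#' (~3 kyr between the European domesticus populations up to 10.6 Myr for
#' Apodemus; the musculus/castaneus split is set at 0.35 Myr, shortly after
#' the 0.45 Myr domesticus split, as only "not long after" is estimated).
#'
#' @return A rooted `ape::phylo` with 10 tips.
#' @export
mouse_taxa_tree <- function() {
  txt <- paste0(
    "(((((((DOM_CB:0.003,DOM_MC:0.003):0.009,DOM_AH:0.012):0.438,",
    "((MUS_KH:0.01,MUS_VI:0.01):0.34,CAS:0.35):0.1):0.75,SPI:1.2):0.5,",
    "SPR:1.7):4.9,MAT:6.6):4,APO:10.6);")
  ape::read.tree(text = txt)
}

#' Specify a phylogenetic transcription-turnover model
#'
#' Generative model for presence/absence of transcription evolving along a
#' phylogeny: each non-core window follows a two-state Markov chain with
#' gain rate `gain` and loss rate `loss` per Myr (stationary presence
#' probability `gain / (gain + loss)`); a conserved core fraction is
#' transcribed in every taxon and expressed `core_multiplier` times higher.
#' Expression per transcribed window is log-normal and shared across taxa;
#' sequencing draws Poisson fragment counts at depth `depth` per sample
#' (taxon x tissue x replicate).
#'
#' Defaults represent a turnover regime in which the intermediate sharing
#' class dominates, the all-taxa class holds roughly a fifth of transcribed
#' windows, and the median transcribed window receives a handful of
#' fragments per taxon — the qualitative regime the analysis pipeline is
#' designed for.
#'
#' @param tree Phylogeny with branch lengths in Myr; default
#'   [mouse_taxa_tree()].
#' @param gain,loss Gain/loss rates per Myr (>= 0).
#' @param rate_sdlog Across-window turnover heterogeneity: each window
#'   scales its gain and loss rates by two independent mean-1 log-normal
#'   multipliers with `sdlog = rate_sdlog` (0 = homogeneous rates, where
#'   every window shares the stationary presence probability
#'   `gain / (gain + loss)`). Heterogeneity makes both the per-window
#'   turnover speed and the stationary presence probability vary across the
#'   genome — a reservoir of rarely-transcribed windows that keeps the
#'   union growing as taxa are added, fast windows that differentiate
#'   population-level splits, and slow intermediate-frequency windows that
#'   retain signal at the deepest splits. This mirrors the observed
#'   coexistence of volatile and conserved transcribed windows across a
#'   tree whose splits span thousands of years to 10 Myr.
#' @param root_p Presence probability at the root; default the stationary
#'   probability of each window's own chain.
#' @param core_fraction Fraction of windows immune to loss (default 0.05).
#' @param core_multiplier Expression multiplier for core windows (default 10).
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters
#'   (default `log(5)`, 1).
#' @param depth Expected fragments per unit expression per sample (default 1).
#' @param n_windows Number of windows (default 10000).
#' @param n_tissues,n_replicates Samples per taxon (default 3 tissues x 1).
#' @param window_size Window size in bp (default 200).
#' @param n_chrom Number of equal chromosomes the windows tile (default 5).
#' @return A `turnover_model` list.
#' @export
turnover_model <- function(tree = mouse_taxa_tree(), gain = 0.5, loss = 2,
                           rate_sdlog = 1.5, root_p = NULL, core_fraction = 0.05,
                           core_multiplier = 10, expr_meanlog = log(5),
                           expr_sdlog = 1, depth = 1, n_windows = 10000L,
                           n_tissues = 3L, n_replicates = 1L,
                           window_size = 200L, n_chrom = 5L) {
  if (gain < 0 || loss < 0) stop("rates must be >= 0", call. = FALSE)
  if (core_fraction < 0 || core_fraction > 1)
    stop("`core_fraction` must lie in [0, 1]", call. = FALSE)
  if (rate_sdlog < 0) stop("`rate_sdlog` must be >= 0", call. = FALSE)
  structure(list(tree = tree, gain = gain, loss = loss,
                 rate_sdlog = rate_sdlog, root_p = root_p,
                 core_fraction = core_fraction,
                 core_multiplier = core_multiplier,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 depth = depth, n_windows = as.integer(n_windows),
                 n_tissues = as.integer(n_tissues),
                 n_replicates = as.integer(n_replicates),
                 window_size = as.integer(window_size),
                 n_chrom = as.integer(n_chrom)),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("Transcription turnover model\n")
  cat("  taxa:", length(x$tree$tip.label), "| windows:", x$n_windows,
      "| tissues:", x$n_tissues, "x replicates:", x$n_replicates, "\n")
  cat(sprintf("  gain %.3g / loss %.3g per Myr (mean stationary presence %.3g), rate sdlog %.3g\n",
              x$gain, x$loss, if (x$gain + x$loss > 0) x$gain / (x$gain + x$loss)
              else NA, x$rate_sdlog))
  cat(sprintf("  core fraction %.3g (x%.3g expression), lambda ~ LogNormal(%.3g, %.3g), depth %.3g\n",
              x$core_fraction, x$core_multiplier, x$expr_meanlog, x$expr_sdlog,
              x$depth))
  invisible(x)
}

#' Evolve true presence states along the phylogeny
#'
#' Simulates the two-state gain/loss Markov chain per window: the root state
#' is Bernoulli (stationary probability by default); along a branch of
#' length `t` the chain transitions with
#' `P(0 -> 1) = pi1 * (1 - exp(-(g + l) t))` and
#' `P(1 -> 0) = (1 - pi1) * (1 - exp(-(g + l) t))`, `pi1 = g / (g + l)`.
#' With rate heterogeneity each window uses its own scaled rates
#' `g_w = g * a_w`, `l_w = l * b_w` (independent mean-1 log-normal
#' multipliers), so both speed and stationary presence vary across windows.
#' Core windows are set present in every taxon.
#'
#' @param model A `turnover_model`.
#' @param seed Optional RNG seed.
#' @return Integer windows-by-taxa 0/1 matrix with attribute `core`
#'   (logical vector marking core windows).
#' @export
evolve_presence <- function(model, seed = NULL) {
  stopifnot(inherits(model, "turnover_model"))
  tr <- ape::reorder.phylo(model$tree, "postorder")
  n <- model$n_windows
  n_tip <- length(tr$tip.label)
  with_local_seed(seed, {
    s <- model$rate_sdlog
    gw <- model$gain * (if (s > 0) stats::rlnorm(n, -s^2 / 2, s) else 1)
    lw <- model$loss * (if (s > 0) stats::rlnorm(n, -s^2 / 2, s) else 1)
    rate <- gw + lw
    pi1 <- ifelse(rate > 0, gw / rate, 0.5)
    root_p <- if (is.null(model$root_p)) pi1 else model$root_p
    node_state <- vector("list", n_tip + tr$Nnode)
    root <- n_tip + 1L
    node_state[[root]] <- stats::rbinom(n, 1L, root_p)
    # postorder edges reversed = parents before children
    for (e in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
      par <- node_state[[p]]
      q <- 1 - exp(-rate * t)
      pflip <- ifelse(par == 1L, (1 - pi1) * q, pi1 * q)
      flip <- stats::runif(n) < pflip
      node_state[[ch]] <- as.integer(xor(par == 1L, flip))
    }
    states <- vapply(seq_len(n_tip), function(i) node_state[[i]], integer(n))
    colnames(states) <- tr$tip.label
    core <- rep(FALSE, n)
    n_core <- round(model$core_fraction * n)
    if (n_core > 0) {
      core[sample.int(n, n_core)] <- TRUE
      states[core, ] <- 1L
    }
    rownames(states) <- seq_len(n) - 1L
    structure(states, core = core)
  })
}

#' Draw fragment counts for simulated presence states
#'
#' Each transcribed window draws one log-normal expression level, shared
#' across taxa (core windows scaled by the core multiplier); every sample
#' (taxon x tissue x replicate) then draws an independent Poisson count
#' with mean `lambda * depth` where the window is present in that taxon,
#' and exactly 0 where absent.
#'
#' @param states Presence matrix from [evolve_presence()].
#' @param model The `turnover_model`.
#' @param seed Optional RNG seed.
#' @return A `simulated_dataset`: list with `windows`, `counts` (a
#'   `count_matrix`), and `truth` (`states`, `core`, `lambda`, `tree`,
#'   `model`).
#' @export
sample_counts <- function(states, model, seed = NULL) {
  stopifnot(inherits(model, "turnover_model"))
  n <- nrow(states)
  taxa <- colnames(states)
  core <- attr(states, "core") %||% rep(FALSE, n)
  with_local_seed(seed, {
    lambda <- stats::rlnorm(n, model$expr_meanlog, model$expr_sdlog)
    lambda[core] <- lambda[core] * model$core_multiplier
    combos <- expand.grid(replicate = seq_len(model$n_replicates),
                          tissue = paste0("tissue", seq_len(model$n_tissues)),
                          taxon = taxa, stringsAsFactors = FALSE)
    counts <- matrix(0L, n, nrow(combos))
    for (j in seq_len(nrow(combos))) {
      on <- states[, combos$taxon[j]] == 1L
      counts[on, j] <- stats::rpois(sum(on), lambda[on] * model$depth)
    }
    ids <- paste(combos$taxon, combos$tissue, combos$replicate, sep = ".")
    colnames(counts) <- ids
    rownames(counts) <- rownames(states)
    samples <- data.frame(sample_id = ids, taxon = combos$taxon,
                          tissue = combos$tissue, replicate = combos$replicate)
    wins <- simulated_windows(model)
    cm <- count_matrix(counts, wins, samples = samples)
    structure(list(windows = wins, counts = cm,
                   truth = list(states = states, core = core, lambda = lambda,
                                tree = model$tree, model = model)),
              class = "simulated_dataset")
  })
}

# Window grid for a simulated genome: n_windows split across n_chrom equal
# chromosomes.
simulated_windows <- function(model) {
  per <- ceiling(model$n_windows / model$n_chrom)
  sizes <- rep(per * model$window_size, model$n_chrom)
  extra <- per * model$n_chrom - model$n_windows
  sizes[model$n_chrom] <- sizes[model$n_chrom] - extra * model$window_size
  names(sizes) <- sprintf("chr%02d", seq_len(model$n_chrom))
  make_windows(sizes, model$window_size)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated turnover dataset:", nrow(x$truth$states), "windows x",
      ncol(x$truth$states), "taxa;",
      ncol(x$counts$counts), "samples\n")
  cat("  core windows:", sum(x$truth$core), "\n")
  invisible(x)
}

#' Simulate genomic (DNA) coverage for common-genome masking
#'
#' Each taxon covers each window independently with probability
#' `1 - dropout`; covered windows receive at least one genomic fragment.
#' This exercises common-genome masking with masks strictly smaller than
#' the window grid.
#'
#' @param model A `turnover_model`.
#' @param dropout Per-taxon per-window dropout probability in [0, 1).
#' @param taxa Taxa to simulate genomes for; default the four most diverged
#'   relatives are typical, but all tree tips are used by default.
#' @param mean_depth Mean genomic fragments per covered window (default 3).
#' @param seed Optional RNG seed.
#' @return A windows-by-taxa genomic `count_matrix`.
#' @export
simulate_genomic_coverage <- function(model, dropout = 0.05,
                                      taxa = model$tree$tip.label,
                                      mean_depth = 3, seed = NULL) {
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  n <- model$n_windows
  with_local_seed(seed, {
    covered <- matrix(stats::rbinom(n * length(taxa), 1L, 1 - dropout),
                      n, length(taxa))
    counts <- covered * (1L + matrix(stats::rpois(n * length(taxa),
                                                  max(0, mean_depth - 1)),
                                     n, length(taxa)))
    colnames(counts) <- taxa
    rownames(counts) <- seq_len(n) - 1L
    count_matrix(counts, simulated_windows(model))
  })
}

#' One-stop simulation of a full dataset
#'
#' Runs [evolve_presence()], [sample_counts()] and
#' [simulate_genomic_coverage()] under a single seed.
#'
#' @param model A `turnover_model`.
#' @param seed RNG seed.
#' @param dropout Genomic dropout (default 0: full-grid mask).
#' @return A `simulated_dataset` with an extra `genomic` element.
#' @export
simulate_dataset <- function(model = turnover_model(), seed = NULL,
                             dropout = 0) {
  with_local_seed(seed, {
    states <- evolve_presence(model)
    ds <- sample_counts(states, model)
    ds$genomic <- simulate_genomic_coverage(model, dropout = dropout)
    ds
  })
}
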
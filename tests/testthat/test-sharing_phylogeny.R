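test_that("phi correlation matches its contingency-table formula", {
  # 2x2 table n11=40, n10=10, n01=10, n00=40 -> (1600-100)/2500 = 0.6
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  cc <- correlation_matrix(cbind(A = x, B = y))
  expect_equal(cc["A", "B"], 0.6)
  # phi is Pearson on binary columns
  expect_equal(cc["A", "B"], cor(x, y))
  # perfect and perfectly negative association
  cc2 <- correlation_matrix(cbind(A = x, B = x, C = 1 - x))
  expect_equal(cc2["A", "B"], 1)
  expect_equal(cc2["A", "C"], -1)
  expect_equal(diag(cc2), c(A = 1, B = 1, C = 1))
})

test_that("zero-variance columns are flagged and recorded as 0", {
  x <- c(1, 0, 1, 0)
  expect_warning(cc <- correlation_matrix(cbind(A = x, B = rep(1, 4))),
                 "zero-variance")
  expect_equal(cc["A", "B"], 0)
  expect_true(attr(cc, "flagged")["A", "B"])
})

test_that("Manhattan distances sum absolute correlation differences", {
  cc <- structure(diag(2), dimnames = list(c("A", "B"), c("A", "B")),
                  class = c("correlation_matrix", "matrix", "array"))
  d <- manhattan_distances(cc)
  expect_equal(d["A", "B"], 2)
  expect_equal(diag(d), c(A = 0, B = 0))
  # identical rows -> distance 0; equals stats::dist on the rows
  set.seed(5)
  p <- as_presence(matrix(rbinom(400, 1, 0.4), ncol = 4,
                          dimnames = list(NULL, LETTERS[1:4])))
  cc2 <- correlation_matrix(p)
  d2 <- manhattan_distances(cc2)
  expect_equal(d2, as.matrix(dist(unclass(cc2), method = "manhattan")))
  expect_true(isSymmetric(d2))
})

test_that("neighbor joining solves the three-point configuration", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
  d[1, 2] <- d[2, 1] <- NaN
  expect_error(neighbor_joining(d), "NA")
})

test_that("neighbor joining recovers a known quartet exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) path lengths
  d <- rbind(A = c(0, 3, 5, 6), B = c(3, 0, 6, 7),
             C = c(5, 6, 0, 7), D = c(6, 7, 7, 0))
  colnames(d) <- rownames(d)
  tr <- neighbor_joining(d)
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # AB|CD split present
  splits <- txturnover:::bipartitions(tr)
  expect_true("C|D" %in% splits || "A|B" %in% splits)
})

test_that("neighbor joining is exact on random additive matrices", {
  for (seed in 1:25) {
    fx <- random_additive(sample(5:10, 1), seed)
    est <- neighbor_joining(fx$dist)
    expect_equal(ape::dist.topo(ape::unroot(fx$tree), est), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(stats::cophenetic(est)[rownames(fx$dist),
                                             colnames(fx$dist)] - fx$dist)),
              1e-9)
  }
})

test_that("relabeling taxa permutes the tree without changing it", {
  fx <- random_additive(7, 99)
  perm <- sample(7)
  d2 <- fx$dist[perm, perm]
  t1 <- neighbor_joining(fx$dist)
  t2 <- neighbor_joining(d2)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(stats::cophenetic(t2)[rownames(fx$dist), colnames(fx$dist)],
               stats::cophenetic(t1)[rownames(fx$dist), colnames(fx$dist)],
               tolerance = 1e-9)
})

test_that("equidistant matrices resolve deterministically", {
  d <- matrix(1, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(attr(t1, "n_clamped"), attr(t2, "n_clamped"))
})

test_that("bootstrap supports are complete on clean signal", {
  ds <- simulate_dataset(turnover_model(n_windows = 5000), seed = 41)
  p <- binarize(ds$counts)
  tr <- bootstrap_supports(p, n_boot = 50, seed = 1)
  sup <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(sup >= 70))
  expect_gte(mean(sup == 100), 0.5)
  # single replicate gives all-or-nothing supports
  tr1 <- bootstrap_supports(p, n_boot = 1, seed = 2)
  sup1 <- as.numeric(tr1$node.label[nzchar(tr1$node.label)])
  expect_true(all(sup1 %in% c(0, 100)))
})

test_that("an indistinguishable taxon pair is a fully supported cherry", {
  set.seed(3)
  base <- matrix(rbinom(600, 1, 0.4), ncol = 3,
                 dimnames = list(NULL, c("X", "Y", "Z")))
  p <- as_presence(cbind(base, W = base[, "X"]))
  tr <- bootstrap_supports(p, n_boot = 25, seed = 4)
  # the only internal split of the quartet separates the {W, X} cherry;
  # canonical keys are oriented away from the first label, so it reads "Y|Z"
  sup <- attr(tr, "support")
  expect_equal(unname(sup[["Y|Z"]]), 100)
})

test_that("variance partition arithmetic follows the min/mean definition", {
  # one taxon with terminal lengths 2, 4, 6; nine others fixed at 1
  taxa <- paste0("t", 1:10)
  mk_tree <- function(len1) {
    tips <- paste0(taxa, ":", c(len1, rep(1, 9)))
    ape::read.tree(text = paste0("(", paste(tips, collapse = ","), ");"))
  }
  trees <- lapply(c(2, 4, 6), mk_tree)
  vp <- txturnover:::partition_from_trees(trees, taxa)
  t1 <- vp$per_taxon[vp$per_taxon$taxon == "t1", ]
  expect_equal(t1$robust, 2)
  expect_equal(t1$variable, 2)
  expect_equal(vp$percent_variable, 100 * 2 / (4 + 9), tolerance = 1e-12)
  # identical replicate trees -> 0% sampling variance
  same <- txturnover:::partition_from_trees(lapply(c(2, 2, 2), mk_tree), taxa)
  expect_equal(same$percent_variable, 0)
})

test_that("replicate presences of pure noise give high sampling variance", {
  set.seed(8)
  reps <- lapply(1:3, function(i)
    as_presence(matrix(rbinom(10 * 60, 1, 0.08), ncol = 10,
                       dimnames = list(NULL, paste0("t", 1:10)))))
  vp <- suppressWarnings(partition_branch_variance(reps))
  expect_gt(vp$percent_variable, 10)
  expect_error(partition_branch_variance(reps[1]), "2 replicate")
  colnames(reps[[2]]) <- paste0("u", 1:10)
  expect_error(partition_branch_variance(reps), "identical taxa")
})

test_that("replicate splitting is disjoint, exhaustive at full size, seeded", {
  set.seed(2)
  cm <- as_counts(matrix(rpois(300, 5), ncol = 3))
  sets <- split_replicates(cm, n_sets = 3, set_size = 100, seed = 9)
  tot <- Reduce(`+`, lapply(sets, function(s) s$counts))
  expect_true(all(tot <= cm$counts))
  expect_equal(unname(colSums(sets[[1]]$counts)), rep(100, 3))
  # exhaustive when sets cover everything
  cm2 <- as_counts(matrix(c(100, 100, 100), ncol = 1))
  sets2 <- split_replicates(cm2, 3, 100, seed = 1)
  expect_equal(Reduce(`+`, lapply(sets2, function(s) s$counts)), cm2$counts)
  # determinism
  sets3 <- split_replicates(cm, 3, 100, seed = 9)
  expect_identical(lapply(sets, `[[`, "counts"), lapply(sets3, `[[`, "counts"))
  expect_error(split_replicates(cm, 3, 1e6), "insufficient")
})
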
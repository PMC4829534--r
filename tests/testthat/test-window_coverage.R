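test_that("window grid tiles chromosomes and drops partial ends", {
  w <- make_windows(c(chr1 = 1000), 200)
  expect_equal(nrow(w), 5)
  expect_equal(w$start, seq(0, 800, by = 200))
  expect_equal(w$end, seq(200, 1000, by = 200))
  expect_equal(w$index, 0:4)

  w2 <- make_windows(c(chr1 = 999), 200)
  expect_equal(nrow(w2), 4)
  expect_equal(max(w2$end), 800)

  expect_equal(nrow(make_windows(c(chr1 = 0, chr2 = 199), 200)), 0)
  expect_equal(nrow(make_windows(setNames(numeric(0), character(0)), 200)), 0)
  expect_error(make_windows(c(chr1 = 100), 0), "window_size")

  # multi-chromosome grids sort by name and keep indices contiguous
  w3 <- make_windows(c(chrB = 600, chrA = 400), 200)
  expect_equal(unique(w3$chrom), c("chrA", "chrB"))
  expect_equal(w3$index, 0:4)
})

test_that("fragments land in the window holding their midpoint", {
  w <- make_windows(c(chr1 = 1000), 200)
  fr <- data.frame(chrom = "chr1",
                   start = c(100, 150, 10),
                   end = c(260, 350, 60),
                   sample_id = "s1")
  cm <- count_fragments(fr, w)
  # midpoints 180, 250, 35 -> windows [0,200), [200,400), [0,200)
  expect_equal(unname(cm$counts[, "s1"]), c(2, 1, 0, 0, 0))
  expect_equal(unname(cm$dropped["s1"]), 0L)
})

test_that("counting conserves fragments and is permutation invariant", {
  w <- make_windows(c(chr1 = 2000, chr2 = 1000), 200)
  set.seed(7)
  n <- 500
  fr <- data.frame(
    chrom = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
    start = st <- floor(runif(n, 0, 2500)),
    end = st + sample(50:300, n, replace = TRUE),
    sample_id = sample(c("a", "b"), n, replace = TRUE))
  cm <- count_fragments(fr, w)
  # conservation: assigned + dropped = input, per sample
  expect_equal(colSums(cm$counts) + cm$dropped, cm$n_input)
  expect_equal(sum(cm$n_input), n)
  # permuting rows gives the identical matrix
  cm2 <- count_fragments(fr[sample(n), ], w)
  expect_identical(cm$counts, cm2$counts)
  # chrX fragments and beyond-grid midpoints are dropped, not lost
  expect_gt(sum(cm$dropped), 0)
})

test_that("malformed fragment intervals are rejected with their row", {
  w <- make_windows(c(chr1 = 1000), 200)
  fr <- data.frame(chrom = "chr1", start = c(10, 50), end = c(60, 50),
                   sample_id = "s1")
  expect_error(count_fragments(fr, w), "row\\(s\\) 2")
  expect_equal(sum(count_fragments(fr[1, ], w)$counts), 1)
})

test_that("empty fragment table yields an all-zero matrix", {
  w <- make_windows(c(chr1 = 1000), 200)
  fr <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   sample_id = character())
  samples <- data.frame(sample_id = "s1", taxon = "A", tissue = NA, replicate = 1)
  cm <- count_fragments(fr, w, samples = samples)
  expect_equal(sum(cm$counts), 0)
  expect_equal(dim(cm$counts), c(5L, 1L))
})

test_that("common-genome mask requires every taxon at the threshold", {
  m <- rbind(c(3, 1, 2, 5), c(3, 0, 2, 5), c(0, 0, 0, 0))
  colnames(m) <- LETTERS[1:4]
  rownames(m) <- 0:2
  mask <- common_genome_mask(m, LETTERS[1:4], min_count = 1)
  expect_equal(as.logical(mask), c(TRUE, FALSE, FALSE))
  # vacuous taxon set keeps everything
  expect_true(all(common_genome_mask(m, character(0))))
  # monotone: adding a required taxon never grows the mask
  m_sub <- common_genome_mask(m, c("A", "C"))
  expect_true(all(which(mask) %in% which(m_sub)))
  expect_error(common_genome_mask(m, c("A", "Z")), "Z")
})

test_that("subsampling hits targets exactly and respects original counts", {
  set.seed(1)
  cm <- as_counts(matrix(rpois(200, 10), ncol = 2))
  out <- normalize_by_subsampling(cm, 500, seed = 3)
  expect_equal(unname(colSums(out$counts)), c(500, 500))
  expect_true(all(out$counts <= cm$counts))
  expect_true(all(out$counts >= 0))
  # full target is the identity
  full <- normalize_by_subsampling(cm, colSums(cm$counts), seed = 3)
  expect_equal(full$counts, cm$counts)
  # reproducible under the same seed
  out2 <- normalize_by_subsampling(cm, 500, seed = 3)
  expect_identical(out$counts, out2$counts)
  expect_error(normalize_by_subsampling(cm, 10 * sum(cm$counts)), "sample")
})

test_that("subsampling follows hypergeometric moments", {
  # two windows of 1000 fragments each, draw 1000: first-window count has
  # mean 500 and the hypergeometric SD sqrt(1000*.5*.5*1000/1999)
  cm <- as_counts(matrix(c(1000, 1000), ncol = 1))
  n_rep <- 3000
  draws <- vapply(seq_len(n_rep), function(i)
    normalize_by_subsampling(cm, 1000, seed = i)$counts[1, 1], numeric(1))
  sd_hyper <- sqrt(1000 * 0.25 * 1000 / 1999)
  expect_lt(abs(mean(draws) - 500), 3 * sd_hyper / sqrt(n_rep))
  # expectation proportional to target/total on an uneven column
  cm2 <- as_counts(matrix(c(4, 0, 6), ncol = 1))
  d2 <- vapply(1:2000, function(i)
    normalize_by_subsampling(cm2, 5, seed = i)$counts[, 1], numeric(3))
  expect_equal(unname(colSums(t(d2)) / 2000), c(2, 0, 3), tolerance = 0.1)
  expect_true(all(colSums(d2) == 5))
})
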
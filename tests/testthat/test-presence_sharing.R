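test_that("binarize applies 'at least tau' semantics and the mask", {
  m <- as_counts(cbind(A = c(0, 10, 99, 100), B = c(1, 9, 100, 5)))
  p1 <- binarize(m, tau = 1)
  expect_equal(unname(p1[, "A"]), c(0, 1, 1, 1))
  p10 <- binarize(m, tau = 10)
  expect_equal(unname(p10[, "A"]), c(0, 1, 1, 1))
  expect_equal(unname(p10[, "B"]), c(0, 0, 1, 0))
  p100 <- binarize(m, tau = 100)
  expect_equal(unname(p100[, "A"]), c(0, 0, 0, 1))
  # monotone in tau
  expect_true(all(p100 <= p10), all(p10 <= p1))
  # masking restricts rows
  mask <- structure(c(TRUE, TRUE, FALSE, FALSE), class = "common_genome_mask")
  expect_equal(nrow(binarize(m, 1, mask = mask)), 2)
  expect_error(binarize(m, tau = 0), "tau")
})

test_that("taxon aggregation sums tissues before thresholding", {
  w <- make_windows(c(chr1 = 400), 200)
  counts <- cbind(5, 6, 0, 2)
  colnames(counts) <- c("A.liver", "A.brain", "B.liver", "B.brain")
  rownames(counts) <- 0
  counts <- rbind(counts, 0)
  rownames(counts) <- 0:1
  samples <- data.frame(sample_id = colnames(counts),
                        taxon = rep(c("A", "B"), each = 2),
                        tissue = rep(c("liver", "brain"), 2), replicate = 1)
  cm <- count_matrix(counts, w, samples = samples)
  p <- binarize(cm, tau = 10)
  expect_equal(unname(p[1, ]), c(1, 0))  # A: 5+6 = 11 >= 10; B: 2 < 10
  ps <- binarize(cm, tau = 10, by = "sample")
  expect_equal(ncol(ps), 4)
  expect_equal(sum(ps[1, ]), 0)
})

test_that("coverage fractions are ratios over masked windows with union bound", {
  p <- as_presence(cbind(A = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         B = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1)))
  cf <- coverage_fraction(p)
  expect_equal(unname(cf$per_taxon), c(0.5, 0.1))
  expect_equal(cf$union, 0.6)
  expect_gte(cf$union, max(cf$per_taxon))
  expect_error(coverage_fraction(as_presence(matrix(0L, 0, 2))), "empty")
})

test_that("sharing classes partition transcribed windows", {
  set.seed(11)
  p <- as_presence(matrix(rbinom(10 * 200, 1, 0.3), ncol = 10))
  sh <- classify_sharing(p)
  n_tx <- rowSums(p)
  expect_equal(sum(sh$class_counts), sum(n_tx >= 1))
  expect_equal(unname(sh$class_counts["single"]), sum(n_tx == 1))
  expect_equal(unname(sh$class_counts["all"]), sum(n_tx == 10))
  expect_equal(unname(sh$class_counts["intermediate"]),
               sum(n_tx >= 2 & n_tx <= 9))
  expect_error(classify_sharing(as_presence(matrix(1L, 5, 1))), "2 taxa")
  # boundary classes
  one <- as_presence(rbind(c(1, rep(0, 9)), rep(1, 10), c(1, 1, 1, 1, 1, rep(0, 5))))
  sh1 <- classify_sharing(one)
  expect_equal(sh1$per_window$class, c("single", "all", "intermediate"))
})

test_that("coverage breakdown assigns windows to their highest threshold", {
  p <- as_presence(cbind(A = c(1, 1, 1), B = c(1, 0, 0)))
  counts <- cbind(A = c(5, 50, 150), B = c(1, 0, 0))
  sh <- classify_sharing(p, counts = counts, thresholds = c(1, 10, 100))
  bt <- sh$by_taxon
  a <- bt[bt$taxon == "A", ]
  expect_equal(sum(a$Freq), 3)
  expect_equal(a$Freq[a$class == "all" & a$coverage == ">=1"], 1)
  expect_equal(a$Freq[a$class == "single" & a$coverage == ">=10"], 1)
  expect_equal(a$Freq[a$class == "single" & a$coverage == ">=100"], 1)
})

test_that("taxon-specific high-expression windows are exclusive and strict", {
  m <- rbind(c(60, 0, 0), c(60, 1, 0), c(50, 0, 0), c(51, 0, 0))
  colnames(m) <- c("A", "B", "C")
  rownames(m) <- 0:3
  hits <- taxon_specific_high_expression(m, min_reads = 50)
  expect_equal(hits$index, c("0", "3"))
  expect_equal(unique(hits$taxon), "A")
  expect_equal(hits$count, c(60, 51))
})

test_that("singletons are tracked across tissues and taxa", {
  w <- make_windows(c(chr1 = 600), 200)
  counts <- cbind(c(1, 1, 0), c(3, 0, 0), c(0, 0, 2))
  colnames(counts) <- c("A.liver", "A.brain", "B.liver")
  rownames(counts) <- 0:2
  samples <- data.frame(sample_id = colnames(counts),
                        taxon = c("A", "A", "B"),
                        tissue = c("liver", "brain", "liver"), replicate = 1)
  cm <- count_matrix(counts, w, samples = samples)
  rep_ <- singleton_redetection(cm)$per_sample
  a <- rep_[rep_$sample_id == "A.liver", ]
  expect_equal(a$n_singletons, 2)
  expect_equal(a$frac_redetected, 0.5)  # window 0 seen in A.brain, window 1 nowhere
  expect_equal(a$frac_unique, 0.5)
  expect_equal(a$frac_other_taxon, 0)   # B never re-detects A.liver singletons
  # no singletons -> zero fractions
  none <- singleton_redetection(as_counts(cbind(c(2, 0), c(5, 3))))$per_sample
  expect_equal(none$n_singletons, c(0, 0))
  expect_equal(none$frac_unique, c(0, 0))
})

test_that("Poisson miss probability matches the analytic zero class", {
  expect_equal(detection_miss_probability(1, 1), exp(-1))
  expect_equal(detection_miss_probability(1, 9), exp(-9))
  expect_equal(detection_miss_probability(0, 5), 1)
  # lambda and k trade off exactly; strictly decreasing in both
  expect_equal(detection_miss_probability(2, 3), detection_miss_probability(6, 1))
  lam <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(detection_miss_probability(lam, 2)) < 0))
  expect_error(detection_miss_probability(-1, 1), "lambda")
  expect_error(detection_miss_probability(1, 0), "k")
})

test_that("coverage fraction is non-increasing in tau on simulated data", {
  ds <- simulate_dataset(turnover_model(n_windows = 2000), seed = 21)
  cov <- vapply(c(1, 10, 100), function(tau)
    coverage_fraction(binarize(ds$counts, tau = tau))$per_taxon,
    numeric(10))
  expect_true(all(diff(t(cov)) <= 0))
})

test_that("the all-taxa class is enriched for high-coverage windows", {
  ds <- simulate_dataset(turnover_model(), seed = 31)
  p <- binarize(ds$counts)
  tc <- taxon_counts(ds$counts)
  sh <- classify_sharing(p, counts = tc)
  hi <- rowSums(tc >= 100) > 0
  cls <- sh$per_window$class
  frac_hi_all <- mean(hi[cls == "all" & !is.na(cls)])
  frac_hi_single <- mean(hi[cls == "single" & !is.na(cls)])
  expect_gt(frac_hi_all, frac_hi_single)
})
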
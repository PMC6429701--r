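test_that("the BH recursion and Bonferroni behave as printed", {
  expect_equal(correctPvalues(c(0.9, 0.5, 0.01), "bh"),
               c(0.9, 0.75, 0.03))
  expect_equal(correctPvalues(c(0.9, 0.5, 0.01), "bonferroni"),
               c(1, 1, 0.03))
  expect_identical(correctPvalues(numeric(0), "bh"), numeric(0))
  expect_equal(correctPvalues(0.2, "bh"), 0.2)
  expect_error(correctPvalues(c(0.5, 0), "bh"), "\\(0, 1]")
  expect_error(correctPvalues(1.2, "bh"), "\\(0, 1]")
})

test_that("BH agrees with the independent reference on random vectors", {
  set.seed(99)
  for (k in 1:200) {
    p <- runif(sample(1:50, 1L))
    got <- correctPvalues(p, "bh")
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    expect_equal(got, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("score aggregation of corrected p-values", {
  expect_identical(substitutionScore(numeric(0)), 0)
  expect_identical(substitutionScore(c(1, 1)), 0)
  expect_equal(substitutionScore(0.03), 3.5066, tolerance = 1e-4)
  expect_error(substitutionScore(c(0.5, 0)), "zero")
  # adding a p of 1 never changes the score; increasing any p lowers it
  p <- c(0.2, 0.7)
  expect_equal(substitutionScore(c(p, 1)), substitutionScore(p))
  expect_lt(substitutionScore(c(0.3, 0.7)), substitutionScore(p))
})

test_that("the combined score doubles the substitution part", {
  expect_identical(sssScore(0, 0), 0)
  expect_identical(sssScore(5, 2), 12)
  expect_equal(sssScore(3.5066, 0), 7.0132)
  expect_error(sssScore(-1, 0), "non-negative")
})

test_that("classification respects all three cutoffs", {
  expect_identical(classifySelection(12.8, d = 3), "positive")
  expect_identical(classifySelection(0, d = 3), "conserved")
  expect_identical(classifySelection(5, d = 3), "intermediate")
  expect_identical(classifySelection(5, d = 3, positive_cutoff = 4.5),
                   "positive")
  expect_identical(classifySelection(30, d = 15), "high_divergence")
  expect_identical(classifySelection(2, d = 3), "conserved")  # boundary
  expect_identical(classifySelection(10, d = 3), "positive")  # boundary
})

test_that("the discrepancy region maximises the normalised difference", {
  n <- 30L
  A <- matrix(0, n, n)
  expect_identical(maxDiscrepancyRegion(A, A, 5L)$d_obs, 0)
  expect_identical(maxDiscrepancyRegion(A, A, 5L)$region, c(1L, n))

  # one entry differing by 1: shortest window containing both ends wins
  B <- A; B[10, 18] <- 1; B[18, 10] <- 1
  res <- maxDiscrepancyRegion(A, B, 5L)
  expect_identical(res$region, c(10L, 18L))
  expect_equal(res$d_obs, 1 / 9)

  # exhaustive oracle on a random instance
  set.seed(3)
  P1 <- matrix(runif(n * n, 0, 0.3), n, n); P1 <- (P1 + t(P1)) / 2
  P2 <- matrix(runif(n * n, 0, 0.3), n, n); P2 <- (P2 + t(P2)) / 2
  res <- maxDiscrepancyRegion(P1, P2, 5L)
  brute_best <- -Inf; brute_reg <- NULL
  D <- (P1 - P2)^2
  for (i in 1:(n - 4L)) for (j in (i + 4L):n) {
    s <- 0
    for (a in i:(j - 1L)) for (b in (a + 1L):j) s <- s + D[a, b]
    d <- sqrt(s) / (j - i + 1L)
    if (d > brute_best + 1e-12) { brute_best <- d; brute_reg <- c(i, j) }
  }
  expect_equal(res$d_obs, brute_best, tolerance = 1e-10)
  expect_identical(res$region, as.integer(brute_reg))

  expect_identical(maxDiscrepancyRegion(A, B, 100L)$region, c(1L, n))
  expect_error(maxDiscrepancyRegion(A, matrix(0, 5, 5), 5L),
               "dimension")
})

test_that("substitution p-values are seeded, bounded and sensible", {
  wt <- hairpin_tail(25L)
  pos <- nchar(wt) - 5L  # deep in the unpaired tail
  r1 <- substitutionPvalue(wt, pos, "A", "C", N = 30L, seed = 11)
  r2 <- substitutionPvalue(wt, pos, "A", "C", N = 30L, seed = 11)
  expect_identical(r1$p_raw, r2$p_raw)
  expect_gte(r1$p_raw, 1 / 31)
  expect_lte(r1$p_raw, 1)
  # a tail substitution barely moves the ensemble
  expect_lt(r1$d_obs, 0.01)
  expect_gt(r1$p_raw, 0.5)
  expect_error(substitutionPvalue(wt, pos, "A", "C", N = 0L), "at least 1")
  expect_error(substitutionPvalue(wt, 1L, "C", "A", N = 5L),
               "does not carry")
})
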
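cand_df <- function(start, end, energy, n_pairs = 5L) {
  data.frame(start = start, end = end,
             structure = strrep(".", end - start + 1L),
             energy = energy, n_pairs = n_pairs)
}

test_that("greedy stability selection resolves overlaps", {
  cand <- cand_df(c(10L, 30L), c(60L, 80L), c(-30, -20))
  kept <- selectNonoverlapping(cand)
  expect_identical(kept$energy, -30)

  cand <- cand_df(c(10L, 100L, 200L), c(50L, 150L, 240L),
                  c(-10, -20, -30))
  expect_identical(nrow(selectNonoverlapping(cand)), 3L)

  # equal energies: leftmost wins
  cand <- cand_df(c(40L, 10L), c(90L, 60L), c(-15, -15))
  expect_identical(selectNonoverlapping(cand)$start, 10L)

  # short noise candidates are dropped
  cand <- cand_df(10L, 20L, -5, n_pairs = 2L)
  expect_identical(nrow(selectNonoverlapping(cand)), 0L)
  selected <- selectNonoverlapping(
    cand_df(c(1L, 5L, 200L), c(100L, 120L, 300L), c(-8, -25, -12)))
  expect_true(all(diff(selected$start) > 0))
  ov <- outer(seq_len(nrow(selected)), seq_len(nrow(selected)),
              function(i, j) selected$start[i] <= selected$end[j] &
                             selected$end[i] >= selected$start[j])
  expect_true(all(ov[lower.tri(ov)] == FALSE))
})

test_that("orthologous structures group into blocks within tolerance", {
  rows <- setNames(rep(strrep("ACGU", 75), 3), c("sp1", "sp2", "sp3"))
  fam <- RNAFamily(rows)  # ungapped: columns equal positions
  mk <- function(start, len = 100L)
    cand_df(start, start + len - 1L, -20)
  per <- list(sp1 = mk(100L), sp2 = mk(105L), sp3 = mk(110L))
  blocks <- matchBlocks(per, fam, tolerance = 0.3, min_species = 3L)
  expect_length(blocks, 1L)
  expect_identical(sort(blocks[[1L]]$species), c("sp1", "sp2", "sp3"))

  # only two species share the region: no block
  per2 <- list(sp1 = mk(100L), sp2 = mk(105L), sp3 = mk(250L, 40L))
  expect_length(matchBlocks(per2, fam, 0.3, 3L), 0L)

  # a shift of exactly 30% of the shorter length is still included
  per3 <- list(sp1 = mk(100L), sp2 = mk(130L), sp3 = mk(100L))
  expect_length(matchBlocks(per3, fam, 0.3, 3L), 1L)
  per4 <- list(sp1 = mk(100L), sp2 = mk(131L), sp3 = mk(100L))
  expect_length(matchBlocks(per4, fam, 0.3, 3L), 0L)

  # grouping is independent of species order
  blocks_r <- matchBlocks(rev(per), fam, 0.3, 3L)
  expect_identical(sort(blocks_r[[1L]]$species),
                   sort(blocks[[1L]]$species))
  expect_error(matchBlocks(list(zz = mk(1L)), fam), "absent")
})

test_that("start columns respect the alignment projection", {
  rows <- c(sp1 = "--GGGAAACCCAA", sp2 = "AAGGGAAACCC--",
            sp3 = "AAGGGAAACCCAA")
  fam <- RNAFamily(rows)
  per <- list(sp1 = cand_df(1L, 9L, -10),   # starts at column 3
              sp2 = cand_df(3L, 11L, -10),  # starts at column 3
              sp3 = cand_df(3L, 11L, -10))
  blocks <- matchBlocks(per, fam, tolerance = 0, min_species = 3L)
  expect_length(blocks, 1L)
  expect_true(all(blocks[[1L]]$start_col == 3L))
})

test_that("screening scores identical blocks as conserved", {
  hp <- "GGGCGGGCAAAAGCCCGCCC"
  row <- paste0(strrep("A", 10), hp, strrep("A", 10))
  fam <- identical_family(row, 3L)
  cfg <- runConfig(max_span = 30L, null_samples = 10L, seed = 4)
  blocks <- familyBlocks(fam, cfg)
  expect_gte(length(blocks), 1L)
  screened <- screenBlocks(blocks, fam, cfg)
  first <- screened[[1L]]
  expect_false(first$high_divergence)
  tab <- reportTable(first$report)
  expect_true(all(tab$sss_score == 0))
  expect_true(all(tab$label == "conserved"))
})
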
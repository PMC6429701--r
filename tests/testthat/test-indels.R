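test_that("placement counts follow the combinatorics", {
  s <- "GGGGAAACCC"  # L = 10
  del <- list(kind = "deletion", length = 2L)
  pl <- enumerateIndelPlacements(s, del, consensus_structure =
                                   strrep(".", 10))
  expect_identical(nrow(pl), 9L)
  expect_identical(pl$j, 0:8)
  expect_true(all(nchar(pl$sequence) == 8L))

  ins <- list(kind = "insertion", length = 1L, focal_state = "A")
  pl <- enumerateIndelPlacements(s, ins, consensus_structure =
                                   strrep(".", 10))
  expect_identical(nrow(pl), 11L)
  expect_true(all(nchar(pl$sequence) == 11L))
  expect_error(enumerateIndelPlacements(s,
    list(kind = "deletion", length = 10L)), "smaller than")
  expect_error(enumerateIndelPlacements(s,
    list(kind = "substitution", length = 1L)), "not an indel")
})

test_that("constraints keep unaffected consensus pairs, remapped", {
  s <- "GGGGGAAAAACCCCC"
  struct <- "(((((.....)))))"
  del <- list(kind = "deletion", length = 2L)
  pl <- enumerateIndelPlacements(s, del, consensus_structure = struct)
  # deleting two loop bases (after position 6) keeps all five pairs
  loop_row <- pl[pl$j == 6L, ]
  expect_identical(loop_row$constraint, "(((((...)))))")
  # deleting stem bases removes the affected pairs
  stem_row <- pl[pl$j == 0L, ]
  cst_pairs <- pairTable(chartr(".", ".", stem_row$constraint))
  expect_identical(nrow(cst_pairs), 3L)
})

test_that("a loop-only deletion has no structural impact", {
  s <- "GGGGGAAAAACCCCC"
  struct <- foldSequence(s, pf = FALSE)@mfe_structure
  del <- list(kind = "deletion", length = 2L)
  pl <- enumerateIndelPlacements(s, del, consensus_structure = struct)
  pl <- scoreIndelPlacements(pl)
  expect_identical(pl$delta[pl$j == 6L], 0L)
  expect_identical(pl$phi[pl$j == 6L], pl$psi[pl$j == 6L])
})

test_that("indel p-values combine rank and structural impact", {
  d <- c(5, 0, 1, 0, 0, 0, 2, 0, 0)
  sc <- indelPvalue(d, 1L, l = 10L)
  expect_identical(sc$r, 1L)
  expect_equal(sc$p_rank, 1 / 9)
  expect_equal(sc$p_struc, (40 - 5) / 40)
  expect_equal(sc$p_raw, 1 / 9 + 35 / 40)

  expect_equal(indelPvalue(c(0, 0, 0), 2L, 10L)$p_struc, 1)
  expect_equal(indelPvalue(c(100, 1), 1L, 10L)$p_struc, 1 / 40)
  # ties take the worst rank
  expect_identical(indelPvalue(c(3, 3, 3), 1L, 10L)$r, 3L)
  expect_error(indelPvalue(numeric(0), 1L, 10L), "empty")
})

test_that("tree edit distance is a metric with the documented values", {
  expect_identical(structuralDistance("((....))", "((....))"), 0L)
  expect_identical(structuralDistance("((....))", "........"), 6L)
  expect_identical(structuralDistance("", ""), 0L)
  expect_identical(structuralDistance("....", "(..)"), 3L)
  set.seed(17)
  for (k in 1:20) {
    a <- random_structure(10L); b <- random_structure(10L)
    ab <- structuralDistance(a, strrep(".", nchar(a)))
    expect_gte(ab, 0L)
    b2 <- substr(paste0(b, strrep(".", nchar(a))), 1, nchar(a))
    expect_identical(structuralDistance(a, a), 0L)
  }
  expect_error(structuralDistance("..", "..."), "equal length")
})

test_that("tree edit distance is symmetric on random pairs", {
  set.seed(23)
  for (k in 1:30) {
    a <- random_structure(12L)
    b <- random_structure(12L)
    expect_identical(SSStest:::.tree_edit_cpp(a, b),
                     SSStest:::.tree_edit_cpp(b, a))
  }
})
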
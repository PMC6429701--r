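bg_of <- function(...) {
  rows <- c(...)
  RNAFamily(setNames(rows, sprintf("s%d", seq_along(rows))),
            min_species = 2L)
}

test_that("consensus characters, agreement and the 60% boundary", {
  bg <- bg_of("A", "A", "A", "G", "G")
  prof <- buildConsensus(bg, 0.6)
  expect_identical(prof@chars, "A")
  expect_equal(prof@agreement, 0.6)
  expect_true(prof@well_conserved)  # boundary is >=

  prof <- buildConsensus(bg_of("A", "C", "G", "U", "-"), 0.6)
  expect_equal(prof@agreement, 0.2)
  expect_false(prof@well_conserved)

  # ties break alphabetically, the gap loses against any base
  expect_identical(buildConsensus(bg_of("A", "A", "G", "G"))@chars, "A")
  expect_identical(buildConsensus(bg_of("-", "-", "U", "U"))@chars, "U")
})

test_that("variant calling emits substitutions and merged indels", {
  bg <- bg_of("GGGAAACCC", "GGGAAACCC", "GGGAAACCC", "GGGAAACCC")
  prof <- buildConsensus(bg)
  expect_identical(nrow(callVariants(prof, "GGGAAACCC")), 0L)

  ev <- callVariants(prof, "GGGAAUCCC")
  expect_identical(ev$kind, "substitution")
  expect_identical(ev$col_start, 6L)
  expect_identical(ev$consensus_state, "A")
  expect_identical(ev$focal_state, "U")

  ev <- callVariants(prof, "GGG--ACCC")
  expect_identical(ev$kind, "deletion")
  expect_identical(c(ev$col_start, ev$col_end), c(4L, 5L))
  expect_identical(ev$length, 2L)

  ins_bg <- bg_of("GGG--ACCC", "GGG--ACCC", "GGG--ACCC")
  ev <- callVariants(buildConsensus(ins_bg), "GGGUUACCC")
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$focal_state, "UU")
  expect_error(callVariants(prof, "GGGAAACC"), "length")
})

test_that("substitutions at non-conserved columns are not called", {
  bg <- bg_of("GAGAAACCC", "GCGAAACCC", "GGGAAACCC", "GUGAAACCC")
  prof <- buildConsensus(bg, 0.6)
  expect_false(prof@well_conserved[[2L]])
  ev <- callVariants(prof, "GUGAAACCC")
  expect_identical(nrow(ev), 0L)
})

test_that("a gap run is one event if any column is well conserved", {
  # columns 4-5: col 4 conserved (AAAA), col 5 not (ACGU)
  bg <- bg_of("GGGAAACCC", "GGGACACCC", "GGGAGACCC", "GGGAUACCC")
  prof <- buildConsensus(bg, 0.6)
  expect_true(prof@well_conserved[[4L]])
  expect_false(prof@well_conserved[[5L]])
  ev <- callVariants(prof, "GGG--ACCC")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$length, 2L)
  # a run with no conserved column is dropped
  bg2 <- bg_of("GGGCAACCC", "GGGACACCC", "GGGGUACCC", "GGGUGACCC")
  prof2 <- buildConsensus(bg2, 0.6)
  ev2 <- callVariants(prof2, "GGG--ACCC")
  expect_identical(nrow(ev2), 0L)
})

test_that("substitution count is bounded by conserved mismatches", {
  set.seed(31)
  for (k in 1:10) {
    rows <- replicate(4, paste(sample(c("A", "C", "G", "U"), 20,
                                      replace = TRUE), collapse = ""))
    bg <- bg_of(rows[1], rows[2], rows[3], rows[4])
    prof <- buildConsensus(bg, 0.6)
    focal <- paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE),
                   collapse = "")
    ev <- callVariants(prof, focal)
    n_sub <- sum(ev$kind == "substitution")
    fchar <- strsplit(focal, "")[[1L]]
    bound <- sum(prof@well_conserved & prof@chars != fchar)
    expect_lte(n_sub, bound)
    # calling twice is deterministic
    expect_identical(ev, callVariants(prof, focal))
  }
})

test_that("the well-conserved mask shrinks monotonically in the threshold", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "G", "U"), 50, replace = TRUE),
                collapse = "")
  mutate_some <- function(s, k) {
    ch <- strsplit(s, "")[[1L]]
    at <- sample(length(ch), k)
    ch[at] <- sample(c("A", "C", "G", "U"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  bg <- bg_of(base, mutate_some(base, 2), mutate_some(base, 3),
              mutate_some(base, 2), base)
  prev <- rep(TRUE, 50L)
  for (th in seq(0, 1, by = 0.1)) {
    mask <- buildConsensus(bg, th)@well_conserved
    expect_true(all(prev | !mask))  # mask subset of previous
    prev <- mask
  }
})

test_that("compensatory pair swaps are flagged, loop changes are not", {
  # stem with a G-C pair replaced by A-U in the focal sequence
  cons_row <- "GGGGGAAAACCCCC"
  bg <- bg_of(cons_row, cons_row, cons_row, cons_row)
  prof <- buildConsensus(bg)
  focal <- "GGGGAAAAAUCCCC"  # pair (5,10) G-C -> A-U
  ev <- callVariants(prof, focal)
  expect_identical(nrow(ev), 2L)
  focal_ens <- foldSequence(focal, pf = FALSE)
  bg_cons <- consensusFold(RNAFamily(alignedRows(bg),
                                     min_species = 2L))
  ev <- flagCompensatory(ev, focal_ens, bg_cons, coordinateMap(focal))
  expect_true(all(ev$compensatory))

  # single-sided G-C -> G-U change with the pair intact is also flagged
  focal2 <- "GGGGGAAAACCUCC"
  ev2 <- callVariants(prof, focal2)
  expect_identical(nrow(ev2), 1L)
  ev2 <- flagCompensatory(ev2, foldSequence(focal2, pf = FALSE),
                          bg_cons, coordinateMap(focal2))
  expect_true(ev2$compensatory)

  # a substitution in the hairpin loop (unpaired in both) is retained
  focal3 <- "GGGGGAAGACCCCC"
  ev3 <- callVariants(prof, focal3)
  ev3 <- flagCompensatory(ev3, foldSequence(focal3, pf = FALSE),
                          bg_cons, coordinateMap(focal3))
  expect_false(any(ev3$compensatory))
})
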
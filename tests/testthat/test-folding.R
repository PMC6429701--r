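test_that("folding a strong hairpin recovers the expected ensemble", {
  ens <- foldSequence("GGGGGAAAACCCCC")
  expect_identical(mfeStructure(ens), "(((((....)))))")
  expect_lt(ens@mfe_energy, 0)
  expect_lte(ens@ensemble_free_energy, ens@mfe_energy)
  pp <- pairProbabilities(ens)
  expect_identical(dim(pp), c(14L, 14L))
  expect_true(isTRUE(all.equal(pp, t(pp))))
  expect_true(all(pp >= 0 & pp <= 1 + 1e-9))
  expect_true(all(rowSums(pp) <= 1 + 1e-6))
})

test_that("an unpairable sequence folds open with zero energy", {
  ens <- foldSequence("AAAAAAAAAA")
  expect_identical(mfeStructure(ens), "..........")
  expect_identical(ens@mfe_energy, 0)
})

test_that("centroid contains exactly the pairs above probability 1/2", {
  set.seed(42)
  for (k in 1:5) {
    ens <- foldSequence(randomSequence(60))
    pp <- pairProbabilities(ens)
    cen <- pairTable(ens@centroid_structure)
    if (nrow(cen)) expect_true(all(pp[cen] > 0.5))
    above <- which(upper.tri(pp) & pp > 0.5, arr.ind = TRUE)
    expect_identical(nrow(above), nrow(cen))
  }
})

test_that("ensemble free energy never exceeds the MFE", {
  set.seed(7)
  for (k in 1:5) {
    ens <- foldSequence(randomSequence(50))
    expect_lte(ens@ensemble_free_energy, ens@mfe_energy + 1e-9)
  }
})

test_that("folding is deterministic and rejects empty input", {
  s <- "GCGCGCAAAAGCGCGC"
  e1 <- foldSequence(s); e2 <- foldSequence(s)
  expect_identical(mfeStructure(e1), mfeStructure(e2))
  expect_identical(pairProbabilities(e1), pairProbabilities(e2))
  expect_error(foldSequence(""), "empty")
})

test_that("constrained folding honours, checks and propagates pairs", {
  s <- "GGGGGAAAACCCCC"
  expect_identical(mfeStructure(foldConstrained(s, NULL)),
                   mfeStructure(foldSequence(s)))
  # forcing the native closing pair reproduces the unconstrained MFE
  native <- pairTable(mfeStructure(foldSequence(s)))
  ens <- foldConstrained(s, native[1L, , drop = FALSE])
  expect_identical(mfeStructure(ens), "(((((....)))))")
  # every forced pair must appear even when suboptimal
  shifted <- foldConstrained(s, cbind(2L, 12L))
  expect_true(all(paste(2L, 12L) %in%
                  apply(pairTable(mfeStructure(shifted)), 1L, paste,
                        collapse = " ")))
  expect_error(foldConstrained(s, cbind(c(1L, 1L), c(6L, 10L))),
               "more than one pair")
  expect_error(foldConstrained(s, cbind(c(1L, 3L), c(8L, 12L))),
               "crossing")
  expect_error(foldConstrained(s, cbind(1L, 2L)), "outside|unpairable")
  expect_error(foldConstrained("GGGGGAAAACCCCC", cbind(6L, 9L)),
               "unpairable")
})

test_that("consensus folding of identical rows matches the single fold", {
  s <- "GGGCGCAAAGCGCCC"
  fam <- identical_family(s, 4L)
  cons <- consensusFold(fam)
  expect_identical(mfeStructure(cons), mfeStructure(foldSequence(s)))
  # a two-row background still folds
  bg <- removeFocal(RNAFamily(setNames(rep(s, 3), c("a", "b", "c"))), "a")
  expect_s4_class(consensusFold(bg), "ConsensusEnsemble")
})

test_that("all-gap columns stay unpaired in the consensus structure", {
  fam <- RNAFamily(c(a = "GGGG-GAAAACCCCC", b = "GGGG-GAAAACCCCC",
                     c = "GGGG-GAAAACCCCC"))
  cons <- consensusFold(fam, pf = TRUE)
  expect_identical(substr(mfeStructure(cons), 5L, 5L), ".")
  expect_identical(nchar(mfeStructure(cons)), 15L)
  pp <- cons@consensus_pair_prob
  expect_true(all(pp[5L, ] == 0))
})

test_that("local folding finds an embedded hairpin and nothing else", {
  seq <- paste0(strrep("A", 25), "GGGCGGGC", "GAAAG", "GCCCGCCC",
                strrep("A", 25))
  hits <- localFold(seq, max_span = 40L)
  expect_gt(nrow(hits), 0L)
  chosen <- selectNonoverlapping(hits)
  expect_identical(nrow(chosen), 1L)
  expect_true(chosen$start >= 20 && chosen$end <= nchar(seq) - 19)
  expect_identical(nrow(localFold(strrep("A", 60), 30L)), 0L)
  expect_error(localFold("GGGAAACCC", 3L), "hairpin")
})
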
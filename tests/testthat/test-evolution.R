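test_that("level-5 shapes collapse helices and drop unpaired runs", {
  expect_identical(shape5("(((...)))"), "[]")
  expect_identical(shape5("((..((..))((..))((..))..))"), "[[][][]]")
  expect_identical(shape5("......"), "")
  expect_identical(shape5("((...))...((...))"), "[][]")
  expect_identical(shape5("((..((...))..))"), "[]")  # bulged helix chain
  expect_identical(shape5("((.((...))((...)).))"), "[[][]]")
  expect_error(shape5("((..)"), "unbalanced")
  # deep stems collapse in linear time
  deep <- paste0(strrep("(", 200), "...", strrep(")", 200))
  expect_identical(shape5(deep), "[]")
})

test_that("shape distance is a unit-cost edit distance", {
  expect_identical(shapeDistance("[]", "[]"), 0L)
  expect_identical(shapeDistance("[]", "[[][][]]"), 6L)
  expect_identical(shapeDistance("", "[]"), 2L)
  set.seed(4)
  for (k in 1:10) {
    a <- shape5(random_structure(15L))
    b <- shape5(random_structure(15L))
    expect_identical(shapeDistance(a, b), shapeDistance(b, a))
  }
})

test_that("the stabilising penalty follows its closed form", {
  expect_identical(epsilonStabilizer(-40, -30), 0)
  expect_identical(epsilonStabilizer(-40, -15), 5)
  expect_identical(epsilonStabilizer(-40, -20), 0)  # exact boundary
})

test_that("objective values match the three regimes", {
  ens <- foldSequence("GGGGGAAAACCCCC")
  expect_identical(objectiveValue("rand", ens, ens), 0)
  expect_identical(objectiveValue("neg", ens, ens), 0)
  # with the target met and no energy penalty, pos reduces to gibbs(m)
  expect_equal(objectiveValue("pos", ens, ens, target_shape = "[]"),
               ens@ensemble_free_energy)
  expect_equal(objectiveValue("pos", ens, ens),
               ens@ensemble_free_energy +
                 50 * shapeDistance("[[][][]]", "[]"))
  expect_error(objectiveValue("nope", ens, ens), "arg")
})

test_that("random-drift evolution applies exactly n substitutions", {
  anc <- strrep("ACGU", 10)
  out <- evolveSequence(anc, "rand", n_accepted = 5L, seed = 8)
  expect_identical(out$n_proposals, 5L)
  expect_identical(out$n_accepted, 5L)
  hamming <- sum(strsplit(anc, "")[[1L]] !=
                 strsplit(out$sequence, "")[[1L]])
  expect_lte(hamming, 5L)
  expect_identical(evolveSequence(anc, "rand", 5L, seed = 8)$sequence,
                   out$sequence)
})

test_that("negative selection preserves the ancestral centroid", {
  set.seed(12)
  anc <- randomSequence(80)
  out <- evolveSequence(anc, "neg", n_accepted = 5L, seed = 21)
  anc_c <- foldSequence(anc)@centroid_structure
  out_c <- foldSequence(out$sequence)@centroid_structure
  expect_identical(basePairDistance(anc_c, out_c), 0L)
  expect_gte(out$n_proposals, 5L)
})

test_that("family generation follows both experimental designs", {
  fams <- generateFamilies("rand", n_families = 2L, n_accepted = 3L,
                           seq_length = 60L, seed = 5)
  expect_length(fams, 2L)
  expect_identical(nSpecies(fams[[1L]]), 5L)
  expect_identical(nCols(fams[[1L]]), 60L)
  # same seed regenerates the same data
  again <- generateFamilies("rand", 2L, 3L, 60L, seed = 5)
  expect_identical(alignedRows(fams[[2L]]), alignedRows(again[[2L]]))

  e2 <- generateFamilies("neg", n_families = 1L, n_accepted = 3L,
                         seq_length = 60L, experiment = 2L, seed = 9)[[1L]]
  rows <- alignedRows(e2)
  expect_identical(unname(rows[paste0("ancestral_", 1:4)]),
                   rep(unname(rows[["ancestral_1"]]), 4L))
  expect_identical(attr(e2, "evolved_species"), "derived")
})

test_that("designed Y ancestors fold into the Y shape", {
  y <- designYAncestor(80L, seed = 3)
  expect_identical(nchar(y), 80L)
  expect_identical(shape5(foldSequence(y)@centroid_structure), "[[][]]")
})
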
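test_that("FASTA families round-trip through read and write", {
  fam <- RNAFamily(c(human = "GGGA-ACCC", chimp = "GGGAAACCC",
                     gorilla = "GGG-AACCC"),
                   descriptions = c("a lncRNA", "", ""))
  path <- withr::local_tempfile(fileext = ".fa")
  writeFamily(fam, path)
  back <- readFamily(path)
  expect_identical(alignedRows(back), alignedRows(fam))
  expect_identical(speciesNames(back), speciesNames(fam))
  expect_identical(back@descriptions[1L], "a lncRNA")
})

test_that("reading normalises case and transcribes T to U", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ggtacc-t", ">b", "GGTACC-T", ">c", "ggUacc-u"),
             path)
  fam <- readFamily(path)
  expect_identical(unname(alignedRows(fam)),
                   rep("GGUACC-U", 3L))
})

test_that("undersized or malformed families are rejected", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "GGGAAACCC", ">b", "GGGAAACCC"), path)
  expect_error(readFamily(path), "family too small")
  writeLines(c(">a", "GGGAAACCC", ">b", "GGGAACCC", ">c", "GGGAAACCC"),
             path)
  expect_error(readFamily(path), "unequal")
  writeLines(character(0), path)
  expect_error(readFamily(path), "empty")
  writeLines(c(">a", "GGGAXACCC", ">b", "GGGAAACCC", ">c", "GGGAAACCC"),
             path)
  expect_error(readFamily(path), "IUPAC")
  expect_error(RNAFamily(c(a = "GGG", a = "GGG", b = "GGG")), "unique")
})

test_that("unaligned identical sequences align to a gap-free family", {
  path <- withr::local_tempfile(fileext = ".fa")
  seq <- "GGGCGCAAAGCGCCC"
  writeLines(c(">a", seq, ">b", seq, ">c", seq), path)
  fam <- readFamily(path, aligned = FALSE)
  expect_identical(nCols(fam), nchar(seq))
  expect_false(any(grepl("-", alignedRows(fam), fixed = TRUE)))
})

test_that("coordinate maps relate columns and ungapped positions", {
  m <- coordinateMap("A-CG")
  expect_identical(m$col_to_seq, c(1L, NA_integer_, 2L, 3L))
  expect_identical(m$seq_to_col, c(1L, 3L, 4L))
  expect_true(all(is.na(coordinateMap("----")$col_to_seq)))
  expect_identical(coordinateMap("ACGU")$col_to_seq, 1:4)
  # bijective and monotone on non-gap columns
  row <- "AC--GU-A"
  m <- coordinateMap(row)
  expect_identical(m$col_to_seq[m$seq_to_col],
                   seq_along(m$seq_to_col))
  expect_true(all(diff(m$seq_to_col) > 0))
})

test_that("focal removal keeps columns and partitions the rows", {
  rows <- c(a = "GGGAAACCC", b = "GGGA-ACCC", c = "GG-AAACCC",
            d = "GGGAAACC-", e = "GGGAAACCC")
  fam <- RNAFamily(rows)
  bg <- removeFocal(fam, "c")
  expect_identical(nCols(bg), nCols(fam))
  expect_identical(nSpecies(bg), 4L)
  expect_identical(sort(c(speciesNames(bg), "c")),
                   sort(speciesNames(fam)))
  expect_identical(alignedRows(bg)[["a"]], rows[["a"]])
  expect_error(removeFocal(fam, "nope"), "unknown species")
  # minimum family size forces a two-row background, which is accepted
  three <- RNAFamily(rows[1:3])
  expect_identical(nSpecies(removeFocal(three, "a")), 2L)
})

test_that("all-gap columns survive focal removal", {
  fam <- RNAFamily(c(a = "GG-AA", b = "GG-AA", c = "GGCAA"))
  bg <- removeFocal(fam, "c")
  expect_identical(nCols(bg), 5L)
  expect_identical(substr(alignedRows(bg)[["a"]], 3L, 3L), "-")
})
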
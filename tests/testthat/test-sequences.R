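test_that("repeat notation expands left to right", {
  expect_identical(expand_hp_notation("(010)_2_"), "010010")
  expect_identical(expand_hp_notation("(010)_2"), "010010")
  expect_identical(expand_hp_notation("(010)2"), "010010")
  expect_identical(expand_hp_notation("(1)_7_"), "1111111")
  expect_identical(nchar(expand_hp_notation("1(100)_2_1(001)_5_1")), 24L)
  expect_identical(expand_hp_notation("(1)_12_"), strrep("1", 12))
  expect_identical(expand_hp_notation("0101"), "0101")
})

test_that("malformed repeat notation is rejected with a position", {
  expect_error(expand_hp_notation("(010"), "unbalanced.*position 1")
  expect_error(expand_hp_notation("010)_2_"), "closing.*position 4")
  expect_error(expand_hp_notation("((01)_2_)_3_"), "nested")
  expect_error(expand_hp_notation("(01)"), "missing repeat count")
  expect_error(expand_hp_notation("01x10"), "unexpected character 'x' at position 3")
  expect_error(expand_hp_notation("(0a1)_2_"), "'a' inside group")
})

test_that("HP strings parse under both alphabets and conventions", {
  s <- parse_hp("HHPPHPHPHPHPHP")
  expect_s3_class(s, "hp_seq")
  expect_identical(s$n, 14L)
  expect_identical(which(s$residues == "H"), c(1L, 2L, 5L, 7L, 9L, 11L, 13L))

  b <- parse_hp("110101010101", one_is = "H")
  expect_identical(paste(b$residues, collapse = ""), "HHPHPHPHPHPH")
  expect_identical(sum(b$residues == "H"), 7L)

  inv <- parse_hp("110101010101", one_is = "P")
  expect_identical(sum(inv$residues == "H"), 5L)

  expect_identical(format(parse_hp("1(10)_5_1")), "HHPHPHPHPHPH")
  expect_identical(format(parse_hp("hphp")), "HPHP")
})

test_that("invalid sequence strings are rejected", {
  expect_error(parse_hp(""), "empty")
  expect_error(parse_hp("H0PH1"), "mixed")
  expect_error(parse_hp("HXPH"), "invalid symbol 'X' at position 2")
  expect_error(hp_seq(character(0)), "at least one residue")
  expect_error(hp_seq(c("H", "Q")), "invalid residue")
})

test_that("all 28 packaged benchmarks expand to their stated lengths", {
  b <- hp_benchmarks()
  expect_identical(nrow(b), 28L)
  expect_identical(sum(b$table == 1), 8L)
  expect_identical(sum(b$table == 2), 20L)
  expect_identical(nchar(b$sequence), b$stated_length)
  expect_identical(vapply(b$hp, function(s) s$n, integer(1)), b$stated_length)
  expect_true(all(b$stated_best_energy <= 0, na.rm = TRUE))
  # the only rows without a published energy are the two longest chains
  expect_identical(which(is.na(b$stated_best_energy)), c(7L, 8L))
})

test_that("specific benchmark rows match the published table entries", {
  t1 <- hp_benchmarks(1)
  expect_identical(t1$stated_length[1], 20L)
  expect_identical(t1$stated_best_energy[1], -15L)
  t2 <- hp_benchmarks(2)
  expect_identical(nrow(t2), 20L)
  expect_identical(t2$stated_length[20], 37L)
  expect_identical(t2$stated_best_energy[20], -29L)
  # row 7 of the second set is all-hydrophobic under the 1 -> H convention;
  # its published energy -17 is impossible for an all-polar chain, which
  # pins down the digit convention
  expect_identical(t2$sequence[7], strrep("H", 17))
  expect_identical(t2$stated_best_energy[7], -17L)
})

test_that("sequence files round-trip in both dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tHHPPH", "s2\t1(10)_2_1"), tsv)
  got <- read_hp_sequences(tsv)
  expect_identical(got$label, c("s1", "s2"))
  expect_identical(got$sequence, c("HHPPH", "HHPHPH"))

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "HHPP", "HP", ">b", "PPPP"), fa)
  got <- read_hp_sequences(fa)
  expect_identical(got$label, c("a", "b"))
  expect_identical(got$sequence, c("HHPPHP", "PPPP"))

  expect_error(read_hp_sequences(withr::local_tempfile(fileext = ".x",
                                                       lines = ">only")),
               "no sequence lines")
})
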
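test_that("FASTA reading normalizes T to U and validates the alphabet", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT"), tf)
  rec <- read_its2_fasta(tf)
  expect_equal(rec$seq, "ACGU")

  writeLines(c(">a", "AC", ">a", "GG"), tf)
  expect_warning(rec <- read_its2_fasta(tf), "deduplicated")
  expect_equal(rec$id, c("a", "a_2"))

  writeLines(c(">x", "AC!U"), tf)
  expect_error(read_its2_fasta(tf), "record 'x' at offset 3")

  writeLines(character(0), tf)
  expect_error(read_its2_fasta(tf), "empty")
})

test_that("dot-bracket parsing maps brackets to a valid partner table", {
  p <- parse_dotbracket("((...))")
  expect_equal(which(!is.na(p)), c(1, 2, 6, 7))
  expect_equal(p[1], 7L)
  expect_equal(p[2], 6L)

  expect_true(all(is.na(parse_dotbracket("......."))))
  expect_error(parse_dotbracket("((.)"), "unbalanced at column")
  expect_error(parse_dotbracket("())"), "unbalanced at column 3")
  expect_error(parse_dotbracket("([.)]"), "invalid dot-bracket character")
  expect_error(parse_dotbracket("(.)", "GAC U"), "length")
  expect_error(parse_dotbracket("(.)", "NAC"),
               "ambiguity codes must be unpaired")
})

test_that("render/parse round-trips on random nested structures", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    partner <- its2cbc:::random_structure(n)
    validate_structure(partner, min_loop = 3L)
    db <- render_dotbracket(partner)
    expect_equal(unclass(parse_dotbracket(db)), partner)
  }
})

test_that("structure invariants are enforced", {
  expect_error(validate_structure(c(2L, NA)), "involution")
  expect_error(validate_structure(c(1L, NA)), "self-pairing")
  # crossing pairs (1,3) and (2,4)
  expect_error(validate_structure(c(3L, 4L, 1L, 2L), min_loop = 1L),
               "crossing")
  expect_error(validate_structure(c(2L, 1L), min_loop = 1L), "min_loop")
})

test_that("structured alignment files round-trip losslessly", {
  aln <- its2cbc:::new_structured_alignment(tibble::tibble(
    id = c("a", "b"),
    aseq = c("GGAAACC-", "GG-AACCU"),
    adb = c("((...))-", "((-..)).")
  ))
  tf <- withr::local_tempfile(fileext = ".sa")
  write_structured_alignment(aln, tf)
  back <- read_structured_alignment(tf)
  expect_equal(back$rows, aln$rows)
  expect_equal(back$n_cols, 8L)
  # gap columns stay synchronized between residue and structure lines
  expect_equal(substr(back$rows$aseq[1], 8, 8), "-")
  expect_equal(substr(back$rows$adb[1], 8, 8), "-")

  bad <- aln
  bad$rows$adb[1] <- "((...))"
  expect_error(write_structured_alignment(bad, tf), "length mismatch")
  expect_error(
    its2cbc:::new_structured_alignment(tibble::tibble(
      id = "a", aseq = "AC", adb = "...")),
    "unequal")
  empty <- aln
  empty$rows <- empty$rows[0, ]
  expect_error(write_structured_alignment(empty, tf), "empty")
})
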
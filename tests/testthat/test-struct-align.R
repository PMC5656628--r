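test_that("12-state encoding is bijective with (sequence, structure)", {
  enc <- encode_structure("GAC", "(.)")
  expect_equal(nchar(enc), 3L)
  dec <- decode_structure(enc)
  expect_equal(dec$seq, "GAC")
  expect_equal(dec$db, "(.)")

  expect_equal(encode_structure("ACGU", "...."), "acgu")
  expect_error(encode_structure("ACG", "(((("), "length")

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    partner <- its2cbc:::random_structure(n)
    s <- random_rna(n)
    db <- render_dotbracket(partner)
    expect_equal(decode_structure(encode_structure(s, db)),
                 list(seq = s, db = db))
  }
})

test_that("pairwise alignment is optimal, symmetric and deterministic", {
  x <- encode_structure("GGAAACC", "((...))")
  aln <- align_pair(x, x)
  expect_equal(attr(aln, "score"), 2 * 7)
  expect_false(grepl("-", aln$rows$aseq[1], fixed = TRUE))

  expect_error(align_pair("", x), "non-empty")

  set.seed(17)
  sc <- align_scoring()
  for (rep in 1:12) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pa <- its2cbc:::random_structure(na); pb <- its2cbc:::random_structure(nb)
    a <- encode_structure(random_rna(na), render_dotbracket(pa))
    b <- encode_structure(random_rna(nb), render_dotbracket(pb))
    s_ab <- attr(align_pair(a, b, sc), "score")
    s_ba <- attr(align_pair(b, a, sc), "score")
    expect_equal(s_ab, s_ba)
    expect_equal(s_ab, brute_force_align_score(a, b, sc), info = paste(a, b))
  }
})

test_that("alignment rows degap back to their inputs", {
  run <- default_run()
  aln <- run$aln
  st <- run$st
  for (k in seq_len(nrow(aln$rows))) {
    dg <- its2cbc:::degap_row(aln$rows$aseq[k], aln$rows$adb[k])
    idx <- match(aln$rows$id[k], st$id)
    expect_equal(dg$seq, st$seq[idx])
    expect_equal(dg$db, st$db[idx])
  }
  expect_equal(aln$rows$id, st$id)  # row order equals input order
})

test_that("progressive MSA handles identical and duplicated inputs", {
  rec <- tibble::tibble(id = c("a", "b", "c"),
                        seq = rep("GGAAACC", 3),
                        db = rep("((...))", 3))
  aln <- progressive_msa(rec)
  expect_equal(aln$n_cols, 7L)
  expect_true(all(aln$rows$aseq == "GGAAACC"))

  rec2 <- dplyr::bind_rows(rec, tibble::tibble(id = "a2", seq = "GGAAACC",
                                               db = "((...))"))
  aln2 <- progressive_msa(rec2)
  expect_equal(aln2$rows$aseq[1], aln2$rows$aseq[4])

  expect_error(progressive_msa(rec[1, ]), ">= 2")
  bad_tree <- ape::read.tree(text = "((a,b),(c,zzz));")
  expect_error(progressive_msa(rec2, guide_tree = bad_tree),
               "guide tree leaves")
})

test_that("generator clade sets align with planted columns recovered", {
  run <- default_run()
  aln <- run$aln
  led <- run$sim$truth$ledger
  # strains without length variation must share identical gapping, so the
  # template columns align one-to-one
  no_indel <- setdiff(aln$rows$id,
                      unique(led$strain[led$type %in% c("indel", "insertion")]))
  no_indel <- intersect(no_indel,
                        run$sim$its2$id[run$sim$its2$lineage == 1])
  expect_gte(length(no_indel), 2L)
  rows <- aln$rows[aln$rows$id %in% no_indel, ]
  gap_patterns <- unique(gsub("[^-]", "x", rows$aseq))
  expect_length(gap_patterns, 1L)
})
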
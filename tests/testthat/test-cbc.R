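test_that("base-pair change classification follows the CBC definitions", {
  expect_equal(classify_change(c("G", "C"), c("A", "U")), "CBC")
  expect_equal(classify_change(c("G", "C"), c("G", "U")), "hCBC")
  expect_equal(classify_change(c("G", "C"), c("G", "A")), "nonCBC")
  expect_equal(classify_change(c("G", "C"), c("G", "C")), "identical")
  expect_equal(classify_change(c("G", "C"), c("N", "C")), "notComparable")
})

test_that("classification matches an exhaustive truth table and is symmetric", {
  bases <- c("A", "C", "G", "U")
  combos <- expand.grid(a5 = bases, a3 = bases, b5 = bases, b3 = bases,
                        stringsAsFactors = FALSE)
  # independently derived truth table, straight from the definitions
  valid <- function(x, y) paste0(x, y) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  expected <- with(combos, ifelse(
    a5 == b5 & a3 == b3, "identical",
    ifelse(!valid(a5, a3) | !valid(b5, b3), "nonCBC",
           ifelse(a5 != b5 & a3 != b3, "CBC", "hCBC"))))
  got <- vapply(seq_len(nrow(combos)), function(k) {
    classify_change(c(combos$a5[k], combos$a3[k]),
                    c(combos$b5[k], combos$b3[k]))
  }, character(1))
  expect_equal(got, unname(expected))
  rev_got <- vapply(seq_len(nrow(combos)), function(k) {
    classify_change(c(combos$b5[k], combos$b3[k]),
                    c(combos$a5[k], combos$a3[k]))
  }, character(1))
  expect_equal(got, rev_got)
})

toy_alignment <- function() {
  # two taxa groups differing by one CBC (cols 1/9) and one hCBC (col 2/8)
  its2cbc:::new_structured_alignment(tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    aseq = c("GGCAAAGCC", "GGCAAAGCC", "AGCAAAGUU", "AGCAAAGUU"),
    adb = rep("(((...)))", 4)
  ))
}

test_that("consensus pairs recover shared stems and respect thresholds", {
  aln <- toy_alignment()
  cp <- consensus_pairs(aln, conserved_frac = 0,
                        helices = c("I", "II", "III"))
  expect_equal(nrow(cp), 3L)
  expect_equal(cp$bp_id, 1:3)
  expect_equal(cp$col5, 1:3)
  expect_equal(cp$col3, 9:7)
  # one divergent row + min_frac 1 drops nothing here (all rows paired);
  # unpaired divergence is dropped at min_frac 1
  aln2 <- aln
  aln2$rows$adb[4] <- ".((...))."
  cp2 <- consensus_pairs(aln2, min_frac = 1, conserved_frac = 0)
  expect_equal(cp2$col5, 2:3)
  # per-group conservation keeps lineage-diagnostic columns
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  cp3 <- consensus_pairs(aln, conserved_frac = 0.7, grouping = grp)
  expect_equal(nrow(cp3), 3L)
})

test_that("the CBC matrix is symmetric with consistent position lists", {
  aln <- toy_alignment()
  cp <- consensus_pairs(aln, conserved_frac = 0)
  cm <- cbc_matrix(aln, cp)
  expect_equal(unname(diag(cm$cbc)), rep(0L, 4))
  expect_true(isSymmetric(cm$cbc))
  expect_true(isSymmetric(cm$hcbc))
  for (x in 1:3) for (y in (x + 1):4) {
    expect_length(cm$cbc_ids[[x, y]], cm$cbc[x, y])
    expect_length(cm$hcbc_ids[[x, y]], cm$hcbc[x, y])
    expect_identical(cm$cbc_ids[[x, y]], cm$cbc_ids[[y, x]])
  }
  expect_equal(cm$cbc["a1", "b1"], 1L)
  expect_equal(cm$hcbc["a1", "b1"], 1L)
  expect_equal(cm$cbc["a1", "a2"], 0L)

  # clade-consensus mode
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  cg <- cbc_matrix(aln, cp, grouping = grp)
  expect_equal(cg$cbc["A", "B"], 1L)
  expect_error(cbc_matrix(aln, cp, grouping = grp[-1]), "absent")
})

test_that("adding a duplicate taxon leaves existing cells unchanged", {
  aln <- toy_alignment()
  cp <- consensus_pairs(aln, conserved_frac = 0)
  cm <- cbc_matrix(aln, cp)
  rows2 <- dplyr::bind_rows(aln$rows,
                            dplyr::mutate(aln$rows[1, ], id = "a1bis"))
  aln2 <- its2cbc:::new_structured_alignment(rows2)
  cm2 <- cbc_matrix(aln2, consensus_pairs(aln2, conserved_frac = 0))
  expect_equal(cm2$cbc[aln$rows$id, aln$rows$id], cm$cbc)
  expect_equal(cm2$cbc["a1bis", "a1"], 0L)
})

test_that("diagnostic CBC positions are found between groups", {
  aln <- toy_alignment()
  cp <- consensus_pairs(aln, conserved_frac = 0)
  di <- lineage_diagnostic_cbcs(aln, cp, c("a1", "a2"), c("b1", "b2"))
  expect_equal(di$bp_id, 1L)
  expect_error(lineage_diagnostic_cbcs(aln, cp, c("a1", "a2"),
                                       c("a2", "b1")), "overlap")
})

test_that("the end-to-end pipeline recovers the planted diagnostic CBCs", {
  run <- default_run()
  di <- lineage_diagnostic_cbcs(
    run$aln, run$pairs,
    names(run$lin)[run$lin == "L1"], names(run$lin)[run$lin == "L2"])
  expect_equal(nrow(di), 3L)
  expect_setequal(unique(di$helix), c("II", "III"))
  expect_equal(sum(di$helix == "II"), 1L)
  expect_equal(sum(di$helix == "III"), 2L)
  # the recovered alignment columns are the planted stem positions
  ref <- "L1C1S1"
  row <- run$aln$rows[run$aln$rows$id == ref, ]
  cols <- its2cbc:::row_col_map(row$aseq)
  tdp <- truth_diagnostic_positions(run$sim$truth, ref)
  expect_setequal(match(di$col5, cols), tdp$i)
  expect_setequal(match(di$col3, cols), tdp$j)

  # no CBCs within any clade
  cm <- cbc_matrix(run$aln, run$pairs)
  td <- tidy(cm)
  same <- run$clades[td$taxon1] == run$clades[td$taxon2]
  expect_true(all(td$n_cbc[same] == 0L))
})
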
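test_that("helix annotation labels the planted template design", {
  tm <- make_template()
  ann <- tm$annotation
  expect_true(ann$complete)
  labs <- ann$helices$label
  expect_setequal(labs[!is.na(labs)], c("I", "II", "III", "IIIa", "IV"))
  hel <- ann$helices
  expect_equal(hel$n_pairs[match(c("I", "II", "III", "IIIa", "IV"),
                                 hel$label)],
               c(9L, 8L, 10L, 4L, 7L))
  # IIIa branches off helix III
  expect_equal(hel$label[hel$parent[match("IIIa", hel$label)]], "III")
  expect_equal(unname(ann$spacers[c("I_II", "II_III")]), c(3L, 4L))
})

test_that("a single hairpin yields helix I only with hallmark flags false", {
  ann <- annotate_helices("...(((((.....)))))...")
  expect_false(ann$complete)
  expect_equal(ann$helices$label, "I")
  rep <- check_hallmarks(ann, "AAAGGGGGAAAAACCCCCAAA")
  expect_false(rep$yy$found)
  expect_false(rep$yrry$found)
  expect_equal(rep$agg_score, 0)
})

test_that("hallmark checks find the planted motifs and variants", {
  tm <- make_template()
  rep <- check_hallmarks(tm$annotation, tm$seq)
  expect_true(rep$yy$found)
  expect_equal(rep$yy$bases, c("U", "U"))
  expect_true(rep$yrry$found)
  expect_equal(rep$yrry$motif, "UGGU")
  expect_true(all(rep$spacer_ok))
  expect_false(rep$agg_motif_found)  # AGG at helix IV base: absent by design
  expect_equal(rep$agg_score, 10)
  expect_length(rep$first_two_bp$II, 2L)

  # variants planted by the generator surface in the per-strain reports
  run <- default_run()
  st <- run$st
  meta <- run$sim$its2
  cxu <- meta$id[meta$lineage == 1 & meta$clade == 3]
  expect_true(all(st$yy[st$id %in% cxu] == "CxU"))
  uxc <- meta$id[meta$lineage == 1 & meta$clade == 2 & meta$strain == 4]
  expect_true(all(st$yy[st$id %in% uxc] == "UxC"))
  rest <- setdiff(meta$id, c(cxu, uxc))
  expect_true(all(st$yy[st$id %in% rest] == "UxU"))
  uaau <- meta$id[meta$lineage == 2 & meta$clade == 3]
  expect_true(all(st$yrry[st$id %in% uaau] == "UAAU"))
  expect_true(all(st$yrry[!st$id %in% uaau] == "UGGU"))
})

test_that("hallmark score is monotone in satisfied hallmarks", {
  tm <- make_template()
  full <- check_hallmarks(tm$annotation, tm$seq)$agg_score
  # destroy the Y-Y mismatch (replace the 5' U by A): score drops by the
  # yy weight, never below
  seq2 <- tm$seq
  pos <- check_hallmarks(tm$annotation, tm$seq)$yy$position[1]
  substr(seq2, pos, pos) <- "A"
  degraded <- check_hallmarks(tm$annotation, seq2)$agg_score
  expect_equal(degraded, full - hallmark_config()$weights[["yy"]])
  expect_true(degraded <= full)
})

test_that("structure selection prefers hallmark-bearing candidates", {
  tm <- make_template()
  messy <- fold_optimal(tm$seq, fold_params(pair_scores = c(GC = 3, AU = 2,
                                                            GU = 1),
                                            min_loop = 3L))
  cands <- tibble::tibble(
    db = c(strrep(".", nchar(tm$seq)), tm$db),
    score = c(999, 10), rank = 1:2)
  sel <- select_structure(cands, tm$seq)
  expect_equal(sel$db, tm$db)  # hallmarks beat fold score

  single <- tibble::tibble(db = tm$db, score = 1, rank = 1L)
  expect_equal(select_structure(single, tm$seq)$db, tm$db)

  # all-zero hallmark scores: the higher fold score wins
  zero <- tibble::tibble(
    db = c("...(((((.....)))))...", "....((((.....))))...."),
    score = c(5, 4), rank = 1:2)
  sel0 <- select_structure(zero, "AAAGGGGGAAAAACCCCCAAA")
  expect_equal(sel0$db, zero$db[1])
})

test_that("annotation does not depend on sequence ids", {
  run <- default_run()
  st <- run$st
  a1 <- annotate_helices(parse_dotbracket(st$db[1]))
  expect_identical(a1$helices, st$annotation[[1]]$helices)
})

test_that("homology transfer reproduces the designed strain structures", {
  run <- default_run()
  st <- run$st
  truth <- run$sim$its2
  expect_true(all(st$agg_score == 10))
  expect_gte(mean(st$db == truth$db[match(st$id, truth$id)]), 0.75)
  # transfer keeps each strain's own bases: planted CBC pairs are intact
  tdp <- truth_diagnostic_positions(run$sim$truth, "L2C1S1")
  partner <- parse_dotbracket(st$db[st$id == "L2C1S1"])
  expect_equal(unname(partner[tdp$i]), tdp$j)
})

test_that("structure recovery holds across seeded replicates", {
  # topology-level recovery of the planted template across generator
  # replicates (subset of seeds; the acceptance suite runs more)
  oks <- vapply(2:4, function(sd) {
    sim <- simulate_its2(its2_sim_config(seed = sd))
    ext <- extract_its2(sim$amplicons, sim$truth$flank_model)
    st <- predict_structures(ext)
    mean(st$agg_score == 10)
  }, numeric(1))
  expect_true(all(oks >= 0.95))
})
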
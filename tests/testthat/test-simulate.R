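test_that("the template satisfies every hallmark by construction", {
  tm <- make_template()
  rep <- check_hallmarks(tm$annotation, tm$seq)
  expect_true(rep$yy$found)
  expect_true(rep$yrry$found)
  expect_true(all(rep$spacer_ok))
  expect_true(tm$annotation$complete)
  expect_equal(build_b9(tm$flank5, tm$flank3)$length, 8L)
  # the designed structure is the fold optimum of its own sequence
  expect_identical(fold_optimal(tm$seq)$db, tm$db)
})

test_that("infeasible template geometry errors", {
  expect_error(its2_sim_config(helix_len = c(I = 0L, II = 8L, III = 10L,
                                             IIIa = 4L, III_ap = 4L,
                                             IV = 7L)),
               "length 0")
  expect_error(make_template(its2_sim_config(
    helix_len = c(I = 9L, II = 4L, III = 10L, IIIa = 4L, III_ap = 4L,
                  IV = 7L))), "helix II")
  expect_error(its2_sim_config(planted_cbcs = list(
    list(helix = "II", stem = 99L, to = c("A", "U"), level = "lineage",
         lineage = 2L))), "outside helix")
  expect_error(its2_sim_config(planted_cbcs = list(
    list(helix = "II", stem = 2L, to = c("A", "A"), level = "lineage",
         lineage = 2L))), "not a valid pair")
  expect_error(its2_sim_config(planted_cbcs = list(
    list(helix = "II", stem = 2L, to = c("A", "U"), level = "lineage",
         lineage = 2L),
    list(helix = "II", stem = 2L, to = c("U", "A"), level = "lineage",
         lineage = 2L))), "contradictory")
  # a planted hCBC must change exactly one side
  expect_error(simulate_its2(its2_sim_config(planted_hcbcs = list(
    list(helix = "I", stem = 1L, to = c("C", "G"), level = "lineage",
         lineage = 2L)))), "must change 1")
})

test_that("simulation is deterministic and honest about its ledger", {
  cfg <- its2_sim_config(seed = 1)
  sim1 <- simulate_its2(cfg)
  sim2 <- simulate_its2(cfg)
  expect_identical(sim1$amplicons, sim2$amplicons)
  expect_identical(sim1$truth$ledger, sim2$truth$ledger)

  # replaying the ledger reproduces every strain exactly
  for (id in sim1$truth$strains$id) {
    r <- replay_strain(sim1$truth, id)
    row <- sim1$truth$strains[sim1$truth$strains$id == id, ]
    expect_identical(r$seq, row$seq)
    expect_identical(r$db, row$db)
    expect_identical(r$amplicon, row$amplicon)
  }
})

test_that("zero rates and no plants give strains identical to the consensus", {
  cfg <- its2_sim_config(seed = 3, n_lineages = 1, clades_per_lineage = 1,
                         strains_per_clade = 3,
                         planted_cbcs = list(), planted_hcbcs = list(),
                         mismatch_variants = list(),
                         loop_mut_rate = 0, stem_neutral_rate = 0,
                         indel_rate = 0, flank_mut_rate = 0,
                         lineage_insertion = NULL)
  sim <- simulate_its2(cfg)
  tm <- make_template(cfg)
  expect_true(all(sim$its2$seq == tm$seq))
  expect_true(all(sim$its2$db == tm$db))
})

test_that("planted changes land where the config says", {
  run <- default_run()
  sim <- run$sim
  # lineage 2 strains carry the three lineage-level CBCs in helices II/III
  led <- sim$truth$ledger
  lin2 <- sim$its2$id[sim$its2$lineage == 2]
  for (id in lin2) {
    mine <- led[led$strain == id & led$type == "cbc", ]
    lineage_level <- mine[mine$target %in% c("II", "III") &
                            mine$index %in% c(2L, 9L), ]
    expect_equal(nrow(lineage_level), 3L)
    expect_true(all(c("II", "III") %in% mine$target))
  }
  lin1 <- sim$its2$id[sim$its2$lineage == 1]
  expect_false(any(led$strain %in% lin1 & led$type == "cbc"))

  # the lineage-restricted insertion is 7-9 nt, lineage 2 only
  ins <- led[led$type == "insertion", ]
  expect_setequal(unique(ins$strain), lin2)
  lens <- nchar(ins$to) - nchar(ins$from)
  expect_true(all(lens >= 7 & lens <= 9))
})

test_that("adding strains never perturbs existing ones", {
  a <- simulate_its2(its2_sim_config(seed = 5, strains_per_clade = 2))
  b <- simulate_its2(its2_sim_config(seed = 5, strains_per_clade = 3))
  shared <- a$its2$id
  expect_identical(a$its2$seq,
                   b$its2$seq[match(shared, b$its2$id)])
})
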
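test_that("weighted-pair optimum matches hand-checkable cases", {
  f <- fold_optimal("GGGAAACCC")
  expect_equal(f$score, 9)
  expect_equal(f$db, "(((...)))")
  expect_equal(brute_force_fold("GGGAAACCC")$score, 9)

  f <- fold_optimal("AAAAAA")
  expect_equal(f$score, 0)
  expect_equal(f$db, "......")

  # loop too short to pair
  expect_equal(brute_force_fold("GC")$score, 0)
  # one forced pair
  bf <- brute_force_fold("GAAAC")
  expect_equal(bf$score, 3)
  expect_equal(bf$structures, "(...)")
  expect_error(brute_force_fold(strrep("A", 17)), "length <= 16")
})

test_that("DP optimum equals the exhaustive oracle on random sequences", {
  set.seed(101)
  p <- fold_params(forbid_lonely_pairs = FALSE)
  for (rep in 1:150) {
    s <- random_rna(sample(5:16, 1))
    expect_equal(fold_optimal(s, p)$score, brute_force_fold(s, p)$score,
                 info = s)
  }
})

test_that("folded structures satisfy the structural invariants", {
  set.seed(5)
  for (rep in 1:30) {
    s <- random_rna(sample(10:60, 1))
    f <- fold_optimal(s)
    expect_silent(validate_structure(f$partner, min_loop = 3L))
    # ambiguity codes never pair
    s2 <- paste0(substr(s, 1, 4), "N", substr(s, 6, nchar(s)))
    f2 <- fold_optimal(s2)
    expect_true(is.na(f2$partner[5]))
  }
})

test_that("fold score is invariant under reverse complement", {
  revcomp <- function(x) paste(rev(strsplit(chartr("ACGU", "UGCA", x),
                                            "")[[1]]), collapse = "")
  # under Watson-Crick pairing the pair set maps bijectively; a G-U wobble
  # maps to the non-pairing A-C, so the invariant is stated for WC scoring
  set.seed(23)
  p <- fold_params(pair_scores = c(GC = 3, AU = 2, GU = 0),
                   forbid_lonely_pairs = FALSE)
  for (rep in 1:40) {
    s <- random_rna(sample(8:30, 1))
    expect_equal(fold_optimal(s, p)$score, fold_optimal(revcomp(s), p)$score,
                 info = s)
  }
})

test_that("suboptimal enumeration respects delta, caps and ordering", {
  p0 <- fold_params(subopt_delta = 0, forbid_lonely_pairs = FALSE)
  # two co-optimal registers for the single G-C pair
  co <- enumerate_suboptimal("GAAACAAAC", p0)
  expect_true(all(co$score == max(co$score)))
  expect_setequal(co$db, c("(...)....", "(.......)"))
  expect_equal(nrow(co), 2L)

  p2 <- fold_params(subopt_delta = 2, forbid_lonely_pairs = FALSE)
  sub <- enumerate_suboptimal("GCGCGC", p2)
  expect_true(all(sub$score >= max(sub$score) - 2))
  expect_false(any(duplicated(sub$db)))
  expect_equal(sub$rank, seq_len(nrow(sub)))
  expect_true(all(diff(sub$score) <= 0))

  one <- enumerate_suboptimal("GGGAAACCC",
                              fold_params(max_candidates = 1L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$db, "(((...)))")
})

test_that("the enumerated set always contains every optimal structure score", {
  set.seed(31)
  for (rep in 1:25) {
    s <- random_rna(sample(6:14, 1))
    p <- fold_params(subopt_delta = 0, forbid_lonely_pairs = FALSE)
    bf <- brute_force_fold(s, p)
    en <- enumerate_suboptimal(s, p)
    expect_equal(max(en$score), bf$score, info = s)
    expect_setequal(en$db[en$score == bf$score], bf$structures)
  }
})

test_that("lonely-pair stripping removes exactly the isolated pairs", {
  # a 3-stack helix survives untouched
  partner <- rep(NA_integer_, 14)
  partner[c(1, 2, 3)] <- c(10, 9, 8)
  partner[c(10, 9, 8)] <- c(1, 2, 3)
  expect_equal(its2cbc:::strip_lonely_pairs(partner), partner)
  # an isolated pair is removed
  partner2 <- rep(NA_integer_, 12)
  partner2[4] <- 9; partner2[9] <- 4
  expect_true(all(is.na(its2cbc:::strip_lonely_pairs(partner2))))
})
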
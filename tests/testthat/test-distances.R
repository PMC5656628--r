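aln_from <- function(...) {
  seqs <- c(...)
  its2cbc:::new_structured_alignment(tibble::tibble(
    id = paste0("t", seq_along(seqs)), aseq = seqs,
    adb = strrep(".", nchar(seqs[1]))))
}

test_that("complete-deletion p-distance matches hand-computed values", {
  dm <- p_distance_matrix(aln_from("ACGU", "ACGU"))
  expect_true(all(dm$d == 0))

  dm <- p_distance_matrix(aln_from("ACGU", "ACGA"))
  expect_equal(dm$d["t1", "t2"], 0.25)
  expect_equal(dm$n_sites_used, 4L)

  # the gapped column is removed once, globally
  dm <- p_distance_matrix(aln_from("AC-U", "ACGU", "AAGU"))
  expect_equal(dm$n_sites_used, 3L)
  expect_equal(dm$d["t1", "t3"], 1 / 3)
  expect_equal(dm$d["t2", "t3"], 1 / 3)

  # ambiguity codes count as missing data
  dm <- p_distance_matrix(aln_from("ACNU", "ACGU"))
  expect_equal(dm$n_sites_used, 3L)

  expect_error(p_distance_matrix(aln_from("--", "--")), "no columns")
})

test_that("p-distance is invariant to all-gap columns and matches naive
           counting on gap-free alignments", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    seqs <- vapply(1:4, function(i) random_rna(n), character(1))
    dm <- p_distance_matrix(aln_from(seqs[1], seqs[2], seqs[3], seqs[4]))
    # naive per-pair counter
    for (x in 1:3) for (y in (x + 1):4) {
      cx <- strsplit(seqs[x], "")[[1]]; cy <- strsplit(seqs[y], "")[[1]]
      expect_equal(dm$d[x, y], mean(cx != cy))
    }
    # cross-check against ape on the same gap-free alignment
    mat <- do.call(rbind, strsplit(chartr("U", "T", seqs), ""))
    rownames(mat) <- paste0("t", 1:4)
    ape_d <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "raw"))
    expect_equal(unname(dm$d), unname(ape_d[rownames(dm$d), rownames(dm$d)]),
                 tolerance = 1e-12)
    # append an all-gap column: distances unchanged
    dm2 <- p_distance_matrix(aln_from(paste0(seqs[1], "-"),
                                      paste0(seqs[2], "-"),
                                      paste0(seqs[3], "-"),
                                      paste0(seqs[4], "-")))
    expect_equal(dm2$d, dm$d)
  }
})

test_that("between- and within-group distances summarize cross pairs", {
  dm <- p_distance_matrix(aln_from("ACGU", "ACGA", "AAAA", "ACAA"))
  expect_equal(between_group_distance(dm, "t1", "t2"), dm$d["t1", "t2"])
  expect_equal(between_group_distance(dm, c("t1", "t2"), c("t3", "t4")),
               mean(dm$d[1:2, 3:4]))
  expect_equal(between_group_distance(dm, c("t1", "t2"), c("t3", "t4"),
                                      stat = "max"),
               max(dm$d[1:2, 3:4]))
  expect_error(between_group_distance(dm, c("t1", "t2"), c("t2", "t3")),
               "overlap")
  dm0 <- p_distance_matrix(aln_from("ACGU", "ACGU", "GGGG"))
  expect_equal(between_group_distance(dm0, "t1", "t2"), 0)
  expect_equal(within_group_distance(dm, "t1"), 0)
  expect_equal(within_group_distance(dm, c("t1", "t2")), dm$d["t1", "t2"])
})

test_that("conservation profile applies the majority rule with IUPAC codes", {
  prof <- conservation_profile(aln_from("AAGC", "AAGC", "AGGC", "AGGU"))
  expect_equal(prof$consensus[1], "A")
  expect_equal(prof$max_frac[1], 1)
  # column 2: A/G at 50/50, below 0.7 -> R
  expect_equal(prof$consensus[2], "R")
  # column 4: C at 0.75 still clears the default threshold
  expect_equal(prof$consensus[4], "C")
  prof1 <- conservation_profile(aln_from("AAGC", "AAGC", "AGGC", "AGGU"),
                                threshold = 1)
  expect_equal(prof1$consensus, c("A", "R", "G", "Y"))
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-built additive matrix on 4 taxa: ((a:1,b:2):1,(c:3,d:4):?) style
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5
  d["a", "d"] <- d["d", "a"] <- 6
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 7
  d["c", "d"] <- d["d", "c"] <- 5
  dm <- structure(list(taxa = letters[1:4], d = d, n_sites_used = 10L,
                       deletion = "complete"), class = "p_distance")
  tr <- nj_tree(dm)
  # additive: path lengths reproduce the input distances exactly
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[letters[1:4], letters[1:4]], d, tolerance = 1e-9)

  expect_error(nj_tree(structure(list(taxa = c("a", "b"),
                                      d = d[1:2, 1:2],
                                      n_sites_used = 1L,
                                      deletion = "complete"),
                                 class = "p_distance")), ">= 3")

  # duplicate taxon: zero-length cherry
  dd <- rbind(cbind(d, e = d[, "a"]), e = c(d["a", ], 0))
  dmd <- structure(list(taxa = rownames(dd), d = dd, n_sites_used = 10L,
                        deletion = "complete"), class = "p_distance")
  trd <- nj_tree(dmd)
  cpd <- ape::cophenetic.phylo(trd)
  expect_equal(unname(cpd["a", "e"]), 0, tolerance = 1e-9)
})

test_that("NJ recovers random additive topologies", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  for (rep in 1:10) {
    tr <- random_additive_tree(sample(6:10, 1))
    d <- ape::cophenetic.phylo(tr)
    dm <- structure(list(taxa = rownames(d), d = d[rownames(d), rownames(d)],
                         n_sites_used = 1L, deletion = "complete"),
                    class = "p_distance")
    est <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(est)), 0)
  }
})
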
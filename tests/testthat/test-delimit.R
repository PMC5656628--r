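make_cbc <- function(taxa, cbc, hcbc) {
  K <- max(cbc)
  ids <- matrix(vector("list", length(taxa)^2), length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  for (x in seq_along(taxa)) for (y in seq_along(taxa)) {
    ids[[x, y]] <- if (cbc[x, y] > 0) seq_len(cbc[x, y]) else integer(0)
  }
  hids <- ids
  for (x in seq_along(taxa)) for (y in seq_along(taxa)) {
    hids[[x, y]] <- if (hcbc[x, y] > 0) seq_len(hcbc[x, y]) else integer(0)
  }
  structure(list(taxa = taxa, cbc = cbc, hcbc = hcbc, cbc_ids = ids,
                 hcbc_ids = hids,
                 pairs = tibble::tibble(bp_id = seq_len(max(1, K)))),
            class = "cbc_matrix")
}

make_pd <- function(taxa, d) {
  structure(list(taxa = taxa, d = d, n_sites_used = 100L,
                 deletion = "complete"), class = "p_distance")
}

test_that("delimitation follows the one-CBC rule and never calls 'same' from
           CBC absence alone", {
  taxa <- c("x", "y", "z")
  cbc <- matrix(0L, 3, 3, dimnames = list(taxa, taxa))
  hcbc <- cbc
  cbc["x", "y"] <- cbc["y", "x"] <- 1L
  hcbc["x", "z"] <- hcbc["z", "x"] <- 6L
  d <- matrix(c(0, .1, .05, .1, 0, .08, .05, .08, 0), 3,
              dimnames = list(taxa, taxa))
  calls <- delimit_species(make_cbc(taxa, cbc, hcbc), make_pd(taxa, d))
  get <- function(a, b) calls[calls$taxon1 == a & calls$taxon2 == b, ]
  expect_equal(get("x", "y")$call, "distinct")
  expect_equal(get("x", "z")$call, "not-separable-by-CBC")
  expect_equal(get("x", "z")$n_hcbc, 6L)
  expect_match(get("x", "z")$evidence, "6 hCBC")
  expect_equal(get("y", "z")$call, "not-separable-by-CBC")
})

test_that("identical taxa are called 'same'; monotone in CBC count", {
  taxa <- c("x", "y")
  zero <- matrix(0L, 2, 2, dimnames = list(taxa, taxa))
  d0 <- matrix(0, 2, 2, dimnames = list(taxa, taxa))
  calls <- delimit_species(make_cbc(taxa, zero, zero), make_pd(taxa, d0))
  expect_equal(calls$call, "same")

  for (n in 1:4) {
    cbc <- zero; cbc["x", "y"] <- cbc["y", "x"] <- n
    calls <- delimit_species(make_cbc(taxa, cbc, zero), make_pd(taxa, d0))
    expect_equal(calls$call, "distinct")
  }
})

test_that("taxon mismatches error and reports are written", {
  taxa <- c("x", "y")
  zero <- matrix(0L, 2, 2, dimnames = list(taxa, taxa))
  d0 <- matrix(0, 2, 2, dimnames = list(taxa, taxa))
  expect_error(
    delimit_species(make_cbc(taxa, zero, zero),
                    make_pd(c("x", "w"), `dimnames<-`(d0, list(c("x", "w"),
                                                               c("x", "w"))))),
    "taxa differ")
  calls <- delimit_species(make_cbc(taxa, zero, zero), make_pd(taxa, d0))
  md <- withr::local_tempfile(fileext = ".md")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_delimitation_report(calls, md, tsv)
  txt <- readLines(md)
  expect_true(any(grepl("Identical ITS2: 1", txt)))
  expect_equal(nrow(utils::read.delim(tsv)), 1L)
})
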
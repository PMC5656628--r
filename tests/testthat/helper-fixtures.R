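# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# full default simulation (the study conditions) plus the downstream
# pipeline stages, computed once and reused across test files
default_run <- function() {
  if (is.null(.fixture_env$run)) {
    sim <- simulate_its2(its2_sim_config(seed = 1))
    ext <- extract_its2(sim$amplicons, sim$truth$flank_model)
    st <- predict_structures(ext)
    aln <- progressive_msa(st)
    lin <- stats::setNames(paste0("L", sim$its2$lineage), sim$its2$id)
    clades <- stats::setNames(paste0("L", sim$its2$lineage, "C",
                                     sim$its2$clade), sim$its2$id)
    pairs <- consensus_pairs(aln, grouping = lin)
    .fixture_env$run <- list(sim = sim, ext = ext, st = st, aln = aln,
                             lin = lin, clades = clades, pairs = pairs)
  }
  .fixture_env$run
}

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# independent affine-gap alignment oracle: exhaustive recursion over all
# global alignments of two encoded strings (shares no code with the DP)
brute_force_align_score <- function(x, y, scoring = align_scoring()) {
  sub <- its2cbc:::encoded_submat(scoring)
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  rec <- function(i, j, last) {
    if (i > length(cx) && j > length(cy)) return(0)
    best <- -Inf
    if (i <= length(cx) && j <= length(cy)) {
      best <- max(best, sub[cx[i], cy[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(cx)) {
      cost <- if (last == "x") ge else go + ge
      best <- max(best, cost + rec(i + 1, j, "x"))
    }
    if (j <= length(cy)) {
      cost <- if (last == "y") ge else go + ge
      best <- max(best, cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# random additive (clock-free) tree and its path-length distance matrix
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}
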
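# 12-state sequence+structure alphabet: each position is (base, pairing
# state). Concrete bases A,C,G,U x {unpaired, open, close}; any IUPAC
# ambiguity code is forced unpaired and encoded as 'n'.
ENC_UNPAIRED <- c(A = "a", C = "c", G = "g", U = "u")
ENC_OPEN <- c(A = "A", C = "C", G = "G", U = "U")
ENC_CLOSE <- c(A = "B", C = "D", G = "H", U = "V")
ENC_AMBIG <- "n"
ENC_GAP <- "-"
ENC_ALPHABET <- c(ENC_UNPAIRED, ENC_OPEN, ENC_CLOSE, ENC_AMBIG, ENC_GAP)

#' Alignment scoring parameters
#'
#' Affine-gap scoring over the 12-state sequence+structure alphabet. A
#' column scores `match` when the bases agree and `mismatch` otherwise,
#' minus `structure_mismatch` when the pairing states differ. Gaps cost
#' `gap_open + L * gap_extend` for length `L`.
#'
#' @param match,mismatch Base-level scores (default 2 / -1).
#' @param structure_mismatch Additional penalty when pairing states differ
#'   (default 1, applied as -1).
#' @param gap_open,gap_extend Affine gap penalties (must be <= 0; defaults
#'   -3 / -1).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -1, structure_mismatch = 1,
                          gap_open = -3, gap_extend = -1) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 structure_mismatch = structure_mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Encode a sequence and its structure into the 12-state alphabet
#'
#' Bijective with the (sequence, dot-bracket) pair: `decode_structure()`
#' inverts it exactly.
#'
#' @param seq RNA sequence string.
#' @param db Dot-bracket string of equal length.
#' @return A single encoded string.
#' @examples
#' encode_structure("GAC", "(.)")
#' @export
encode_structure <- function(seq, db) {
  res <- strsplit(toupper(seq_residues(seq)), "")[[1]]
  st <- strsplit(db, "", fixed = TRUE)[[1]]
  if (length(res) != length(st)) {
    stop("sequence and structure lengths differ (", length(res), " vs ",
         length(st), ")", call. = FALSE)
  }
  out <- character(length(res))
  for (k in seq_along(res)) {
    b <- res[k]
    if (!b %in% c("A", "C", "G", "U")) {
      out[k] <- ENC_AMBIG
    } else {
      out[k] <- switch(st[k], "." = ENC_UNPAIRED[[b]], "(" = ENC_OPEN[[b]],
                       ")" = ENC_CLOSE[[b]],
                       stop("invalid structure character '", st[k], "'",
                            call. = FALSE))
    }
  }
  paste(out, collapse = "")
}

#' @rdname encode_structure
#' @param encoded An encoded string (gaps allowed).
#' @return For `decode_structure()`, a list with `seq` and `db` (gap
#'   characters pass through to both).
#' @export
decode_structure <- function(encoded) {
  chars <- strsplit(encoded, "", fixed = TRUE)[[1]]
  seq <- character(length(chars))
  db <- character(length(chars))
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == ENC_GAP) { seq[k] <- "-"; db[k] <- "-"; next }
    if (ch == ENC_AMBIG) { seq[k] <- "N"; db[k] <- "."; next }
    if (ch %in% ENC_UNPAIRED) {
      seq[k] <- names(ENC_UNPAIRED)[ENC_UNPAIRED == ch]; db[k] <- "."
    } else if (ch %in% ENC_OPEN) {
      seq[k] <- names(ENC_OPEN)[ENC_OPEN == ch]; db[k] <- "("
    } else if (ch %in% ENC_CLOSE) {
      seq[k] <- names(ENC_CLOSE)[ENC_CLOSE == ch]; db[k] <- ")"
    } else {
      stop("unknown encoded character '", ch, "'", call. = FALSE)
    }
  }
  list(seq = paste(seq, collapse = ""), db = paste(db, collapse = ""))
}

# substitution matrix over the encoded alphabet (including gap state, used
# for profile columns that contain gaps)
encoded_submat <- function(s) {
  syms <- unname(ENC_ALPHABET)
  base_of <- function(ch) {
    if (ch %in% ENC_UNPAIRED) return(names(ENC_UNPAIRED)[ENC_UNPAIRED == ch])
    if (ch %in% ENC_OPEN) return(names(ENC_OPEN)[ENC_OPEN == ch])
    if (ch %in% ENC_CLOSE) return(names(ENC_CLOSE)[ENC_CLOSE == ch])
    ch
  }
  state_of <- function(ch) {
    if (ch %in% ENC_UNPAIRED || ch == ENC_AMBIG) return("u")
    if (ch %in% ENC_OPEN) return("o")
    if (ch %in% ENC_CLOSE) return("c")
    "-"
  }
  m <- matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
  for (x in syms) {
    for (y in syms) {
      if (x == ENC_GAP && y == ENC_GAP) { m[x, y] <- 0; next }
      if (x == ENC_GAP || y == ENC_GAP) { m[x, y] <- s$gap_extend; next }
      bx <- base_of(x); by <- base_of(y)
      base_sc <- if (bx == by && bx %in% c("A", "C", "G", "U")) s$match else s$mismatch
      struct_sc <- if (state_of(x) == state_of(y)) 0 else -s$structure_mismatch
      m[x, y] <- base_sc + struct_sc
    }
  }
  m
}

profile_matrix <- function(encoded_rows, submat) {
  syms <- rownames(submat)
  mat <- vapply(encoded_rows,
                function(r) strsplit(r, "", fixed = TRUE)[[1]],
                character(nchar(encoded_rows[1])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  ncol_aln <- nrow(mat)  # vapply gives positions in rows
  prof <- matrix(0, length(syms), ncol_aln, dimnames = list(syms, NULL))
  for (cc in seq_len(ncol_aln)) {
    tab <- table(factor(mat[cc, ], levels = syms))
    prof[, cc] <- as.numeric(tab) / sum(tab)
  }
  prof
}

new_structured_alignment <- function(rows) {
  stopifnot(all(c("id", "aseq", "adb") %in% names(rows)))
  nc <- unique(nchar(rows$aseq))
  if (length(nc) != 1L || any(nchar(rows$adb) != nc)) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  structure(list(rows = tibble::as_tibble(rows), n_cols = nc),
            class = "structured_alignment")
}

#' @export
print.structured_alignment <- function(x, ...) {
  cat("Structured alignment:", nrow(x$rows), "rows x", x$n_cols, "columns\n")
  invisible(x)
}

degap_row <- function(aseq, adb) {
  keep <- strsplit(aseq, "", fixed = TRUE)[[1]] != "-"
  list(seq = paste(strsplit(aseq, "")[[1]][keep], collapse = ""),
       db = paste(strsplit(adb, "")[[1]][keep], collapse = ""))
}

#' Pairwise sequence+structure alignment
#'
#' Optimal global alignment of two encoded sequence+structure strings under
#' affine-gap scoring, with a deterministic tie-break (diagonal, then up).
#'
#' @param x,y Encoded strings (see [encode_structure()]) or lists with
#'   `seq`/`db` fields.
#' @param scoring An [align_scoring()].
#' @return A `structured_alignment` with two rows (ids `x`, `y`) and a
#'   `score` attribute.
#' @export
align_pair <- function(x, y, scoring = align_scoring()) {
  if (is.list(x)) x <- encode_structure(x$seq, x$db)
  if (is.list(y)) y <- encode_structure(y$seq, y$db)
  if (nchar(x) == 0L || nchar(y) == 0L) {
    stop("align_pair requires non-empty inputs", call. = FALSE)
  }
  sub <- encoded_submat(scoring)
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  S <- sub[cx, cy, drop = FALSE]
  res <- affine_align_cpp(S, scoring$gap_open, scoring$gap_extend)
  gx <- ifelse(res$ai == 0L, ENC_GAP, cx[pmax(res$ai, 1L)])
  gy <- ifelse(res$bi == 0L, ENC_GAP, cy[pmax(res$bi, 1L)])
  dx <- decode_structure(paste(gx, collapse = ""))
  dy <- decode_structure(paste(gy, collapse = ""))
  out <- new_structured_alignment(tibble::tibble(
    id = c("x", "y"),
    aseq = c(dx$seq, dy$seq),
    adb = c(dx$db, dy$db)
  ))
  attr(out, "score") <- res$score
  out
}

# align two profiles (lists with rows tibble + encoded rows) and return the
# merged profile alignment
merge_profiles <- function(p1, p2, submat, scoring) {
  S <- t(p1$prof) %*% submat %*% p2$prof
  res <- affine_align_cpp(S, scoring$gap_open, scoring$gap_extend)
  expand <- function(rows_enc, idx) {
    vapply(rows_enc, function(r) {
      chars <- strsplit(r, "", fixed = TRUE)[[1]]
      paste(ifelse(idx == 0L, ENC_GAP, chars[pmax(idx, 1L)]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  enc1 <- expand(p1$enc, res$ai)
  enc2 <- expand(p2$enc, res$bi)
  list(ids = c(p1$ids, p2$ids), enc = c(enc1, enc2))
}

#' Progressive multiple sequence+structure alignment
#'
#' Builds a guide tree by neighbor joining on p-distances derived from
#' preliminary sequence-only pairwise alignments (or uses a supplied tree),
#' then merges profiles along the tree with the 12-state affine-gap scorer.
#' Structures are fixed inputs: columns are never re-folded after
#' alignment.
#'
#' @param records Tibble with columns `id`, `seq`, `db`.
#' @param scoring An [align_scoring()].
#' @param guide_tree Optional `phylo` guide tree whose tip labels match
#'   `records$id`.
#' @return A `structured_alignment`; row order equals input order.
#' @export
progressive_msa <- function(records, scoring = align_scoring(),
                            guide_tree = NULL) {
  stopifnot(all(c("id", "seq", "db") %in% names(records)))
  if (nrow(records) < 2L) stop("progressive_msa requires >= 2 records", call. = FALSE)
  sub <- encoded_submat(scoring)
  enc <- purrr::map2_chr(records$seq, records$db, encode_structure)
  leaves <- purrr::map(seq_len(nrow(records)), function(k) {
    list(ids = records$id[k], enc = enc[k],
         prof = profile_matrix(enc[k], sub))
  })
  names(leaves) <- records$id
  if (nrow(records) == 2L) {
    merged <- merge_profiles(leaves[[1]], leaves[[2]], sub, scoring)
  } else {
    if (is.null(guide_tree)) {
      guide_tree <- guide_tree_from_seqs(records)
    } else {
      stopifnot(inherits(guide_tree, "phylo"))
      missing <- setdiff(guide_tree$tip.label, records$id)
      extra <- setdiff(records$id, guide_tree$tip.label)
      if (length(missing) > 0L || length(extra) > 0L) {
        stop("guide tree leaves do not match record ids: ",
             paste(c(missing, extra), collapse = ", "), call. = FALSE)
      }
    }
    tr <- ape::root(guide_tree, outgroup = guide_tree$tip.label[1],
                    resolve.root = TRUE)
    merged <- merge_node(tr, ape::Ntip(tr) + 1L, leaves, sub, scoring)
  }
  dec <- purrr::map(merged$enc, decode_structure)
  rows <- tibble::tibble(id = merged$ids,
                         aseq = purrr::map_chr(dec, "seq"),
                         adb = purrr::map_chr(dec, "db"))
  rows <- rows[match(records$id, rows$id), ]
  new_structured_alignment(rows)
}

merge_node <- function(tree, node, leaves, submat, scoring) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) {
    return(leaves[[tree$tip.label[node]]])
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  profs <- purrr::map(kids, merge_node, tree = tree, leaves = leaves,
                      submat = submat, scoring = scoring)
  acc <- profs[[1]]
  for (k in seq_along(profs)[-1]) {
    merged <- merge_profiles(acc, profs[[k]], submat, scoring)
    acc <- list(ids = merged$ids, enc = merged$enc,
                prof = profile_matrix(merged$enc, submat))
  }
  acc
}

# preliminary sequence-only guide tree: pairwise global alignments via
# Biostrings, p-distance = 1 - fractional identity, NJ topology
guide_tree_from_seqs <- function(records) {
  n <- nrow(records)
  seqs <- Biostrings::RNAStringSet(records$seq)
  names(seqs) <- records$id
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -1, baseOnly = FALSE, type = "RNA")
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[(i + 1L):n], seqs[[i]], type = "global",
      substitutionMatrix = submat, gapOpening = 3, gapExtension = 1)
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - Biostrings::pid(aln) / 100
  }
  ape::nj(stats::as.dist(d))
}
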
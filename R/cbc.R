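#' Classify a base-pair change between two structures
#'
#' A double-sided change of a paired nucleotide pair that retains pairing
#' (Watson-Crick or wobble on both sides of the comparison) is a
#' compensatory base change (CBC); a single-sided change retaining pairing
#' is a hemi-CBC (hCBC); a change that destroys (or lacks) pairing is a
#' non-CBC. IUPAC-ambiguous bases make the comparison `notComparable`.
#' The classification is symmetric in its two arguments.
#'
#' @param a,b Length-2 character vectors `(base5, base3)`, or 2-character
#'   strings.
#' @return One of `"identical"`, `"CBC"`, `"hCBC"`, `"nonCBC"`,
#'   `"notComparable"`.
#' @examples
#' classify_change(c("G", "C"), c("A", "U")) # CBC
#' classify_change(c("G", "C"), c("G", "U")) # hCBC
#' classify_change(c("G", "C"), c("G", "A")) # nonCBC
#' @export
classify_change <- function(a, b) {
  a <- unlist(strsplit(toupper(paste(a, collapse = "")), ""))
  b <- unlist(strsplit(toupper(paste(b, collapse = "")), ""))
  stopifnot(length(a) == 2L, length(b) == 2L)
  if (!all(c(a, b) %in% c("A", "C", "G", "U"))) return("notComparable")
  if (identical(a, b)) return("identical")
  va <- is_valid_pair(a[1], a[2])
  vb <- is_valid_pair(b[1], b[2])
  if (!va || !vb) return("nonCBC")
  ndiff <- sum(a != b)
  if (ndiff == 2L) "CBC" else "hCBC"
}

# per-row helpers on a structured alignment -------------------------------

# map degapped sequence positions to alignment columns for one row
row_col_map <- function(aseq) which(strsplit(aseq, "", fixed = TRUE)[[1]] != "-")

# base characters of a row by alignment column
row_chars <- function(aseq) strsplit(aseq, "", fixed = TRUE)[[1]]

# pairs of one row in alignment-column coordinates
row_pairs_cols <- function(aseq, adb) {
  dg <- degap_row(aseq, adb)
  partner <- parse_dotbracket(dg$db)
  cols <- row_col_map(aseq)
  pr <- structure_pairs(partner)
  tibble::tibble(c5 = cols[pr$i], c3 = cols[pr$j], i = pr$i, j = pr$j)
}

#' Consensus base pairs of a structured alignment
#'
#' Operationalizes "conserved regions of helices I, II and III": a column
#' pair is a consensus pair when it is paired in at least `min_frac` of
#' rows, both columns are at least `conserved_frac` base-conserved (among
#' non-gap symbols), the pair lies in one of the requested helices (by
#' per-row annotation majority), and the retained set is consistently
#' nested (crossing pairs are dropped 5' to 3', deterministically).
#' Consensus pairs are numbered `1..K` in 5' to 3' order of their 5'
#' column; these bp ids are the position ids used in CBC reports.
#'
#' @param aln A `structured_alignment`.
#' @param min_frac Minimum fraction of rows pairing the two columns
#'   (default 0.9).
#' @param conserved_frac Minimum majority-base fraction per column
#'   (default 0.7).
#' @param helices Helix labels to keep (default I, II, III).
#' @param config A [hallmark_config()] for per-row helix annotation.
#' @param grouping Optional named character vector mapping row ids to
#'   lineage (or clade) labels. When given, the conservation filter is
#'   applied within each group - consensus diagrams are drawn per lineage,
#'   and a globally applied majority rule would discard exactly the
#'   lineage-diagnostic positions the analysis is after.
#' @return A tibble: `bp_id`, `col5`, `col3`, `helix`, `frac`.
#' @export
consensus_pairs <- function(aln, min_frac = 0.9, conserved_frac = 0.7,
                            helices = c("I", "II", "III"),
                            config = hallmark_config(), grouping = NULL) {
  stopifnot(inherits(aln, "structured_alignment"))
  rows <- aln$rows
  nr <- nrow(rows)
  per_row <- purrr::map(seq_len(nr), function(k) {
    pc <- row_pairs_cols(rows$aseq[k], rows$adb[k])
    dg <- degap_row(rows$aseq[k], rows$adb[k])
    ann <- annotate_helices(parse_dotbracket(dg$db), config)
    hel <- ann$helices
    lab <- rep(NA_character_, nrow(pc))
    for (h in seq_len(nrow(hel))) {
      pp <- hel$pairs[[h]]
      hit <- match(paste(pc$i, pc$j), paste(pp$i, pp$j))
      lab[!is.na(hit)] <- hel$label[h]
    }
    pc$helix <- lab
    pc
  })
  tall <- dplyr::bind_rows(per_row)
  if (nrow(tall) == 0L) {
    warning("no pairs in alignment", call. = FALSE)
    return(tibble::tibble(bp_id = integer(), col5 = integer(),
                          col3 = integer(), helix = character(),
                          frac = numeric()))
  }
  cons <- dplyr::summarise(
    dplyr::group_by(tall, .data$c5, .data$c3),
    frac = dplyr::n() / nr,
    helix = names(sort(table(.data$helix), decreasing = TRUE))[1] %||% NA_character_,
    .groups = "drop")
  cons <- dplyr::filter(cons, .data$frac >= min_frac, .data$helix %in% helices)
  # conservation filter on both columns (per group when a grouping is given)
  charmat <- t(vapply(rows$aseq, function(s) row_chars(s),
                      character(aln$n_cols)))
  rownames(charmat) <- rows$id
  col_frac <- function(m) apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    max(table(col)) / length(col)
  })
  if (is.null(grouping)) {
    col_cons <- col_frac(charmat)
  } else {
    miss <- setdiff(rows$id, names(grouping))
    if (length(miss) > 0L) {
      stop("rows absent from grouping: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    per_group <- vapply(unique(unname(grouping[rows$id])), function(g) {
      col_frac(charmat[rows$id[grouping[rows$id] == g], , drop = FALSE])
    }, numeric(aln$n_cols))
    col_cons <- apply(per_group, 1, min)
  }
  cons <- dplyr::filter(cons, col_cons[.data$c5] >= conserved_frac,
                        col_cons[.data$c3] >= conserved_frac)
  cons <- dplyr::arrange(cons, .data$c5)
  # enforce consistent nesting (drop crossers, 5'->3' greedy)
  keep <- rep(TRUE, nrow(cons))
  if (nrow(cons) > 1L) {
    kept <- cons[0, ]
    for (t in seq_len(nrow(cons))) {
      crosses <- any(kept$c5 < cons$c5[t] & cons$c5[t] < kept$c3 &
                       kept$c3 < cons$c3[t]) ||
        any(cons$c5[t] < kept$c5 & kept$c5 < cons$c3[t] &
              cons$c3[t] < kept$c3)
      keep[t] <- !crosses
      if (!crosses) kept <- dplyr::bind_rows(kept, cons[t, ])
    }
  }
  cons <- cons[keep, ]
  if (nrow(cons) == 0L) warning("no consensus pairs retained", call. = FALSE)
  tibble::tibble(bp_id = seq_len(nrow(cons)), col5 = cons$c5, col3 = cons$c3,
                 helix = cons$helix, frac = cons$frac)
}

# majority symbol per column within a group of rows (base beats gap on ties,
# then alphabetic)
consensus_row <- function(charmat) {
  apply(charmat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab[tab == max(tab)])
    bases <- setdiff(top, "-")
    if (length(bases) > 0L) sort(bases)[1] else "-"
  })
}

#' Pairwise CBC/hCBC matrix over consensus base pairs
#'
#' For every pair of taxa (or of clade consensus sequences when a grouping
#' is supplied), classifies each consensus base pair and tallies CBCs and
#' hCBCs together with the bp ids at which they occur. Counting is
#' phenetic (pairwise, no ancestral-state reconstruction). Positions with
#' a gap or ambiguity in either sequence are not comparable and are
#' excluded from counts.
#'
#' @param aln A `structured_alignment`.
#' @param pairs Consensus pairs from [consensus_pairs()].
#' @param grouping Optional named character vector mapping every row id to
#'   a clade label; cells are then computed between clade majority-consensus
#'   sequences.
#' @return An object of class `cbc_matrix`: `taxa`, symmetric integer
#'   matrices `cbc` and `hcbc`, list matrices `cbc_ids`/`hcbc_ids`, and
#'   `pairs`.
#' @export
cbc_matrix <- function(aln, pairs, grouping = NULL) {
  stopifnot(inherits(aln, "structured_alignment"))
  rows <- aln$rows
  charmat <- t(vapply(rows$aseq, row_chars, character(aln$n_cols)))
  rownames(charmat) <- rows$id
  if (!is.null(grouping)) {
    miss <- setdiff(rows$id, names(grouping))
    if (length(miss) > 0L) {
      stop("taxa absent from grouping: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    taxa <- unique(unname(grouping[rows$id]))
    charmat <- t(vapply(taxa, function(g) {
      consensus_row(charmat[rows$id[grouping[rows$id] == g], , drop = FALSE])
    }, character(aln$n_cols)))
    rownames(charmat) <- taxa
  } else {
    taxa <- rows$id
  }
  nt <- length(taxa)
  if (nt < 2L) stop("cbc_matrix requires >= 2 taxa", call. = FALSE)
  K <- nrow(pairs)
  b5 <- charmat[, pairs$col5, drop = FALSE]
  b3 <- charmat[, pairs$col3, drop = FALSE]
  cbc <- matrix(0L, nt, nt, dimnames = list(taxa, taxa))
  hcbc <- cbc
  cbc_ids <- matrix(vector("list", nt * nt), nt, nt,
                    dimnames = list(taxa, taxa))
  hcbc_ids <- cbc_ids
  if (nt >= 2L && K > 0L) {
    for (x in seq_len(nt - 1L)) {
      for (y in (x + 1L):nt) {
        cats <- vapply(seq_len(K), function(k) {
          classify_change(c(b5[x, k], b3[x, k]), c(b5[y, k], b3[y, k]))
        }, character(1))
        ic <- pairs$bp_id[cats == "CBC"]
        ih <- pairs$bp_id[cats == "hCBC"]
        cbc[x, y] <- cbc[y, x] <- length(ic)
        hcbc[x, y] <- hcbc[y, x] <- length(ih)
        cbc_ids[[x, y]] <- cbc_ids[[y, x]] <- ic
        hcbc_ids[[x, y]] <- hcbc_ids[[y, x]] <- ih
      }
    }
  }
  structure(list(taxa = taxa, cbc = cbc, hcbc = hcbc, cbc_ids = cbc_ids,
                 hcbc_ids = hcbc_ids, pairs = pairs),
            class = "cbc_matrix")
}

#' @export
print.cbc_matrix <- function(x, ...) {
  cat("CBC matrix over", length(x$taxa), "taxa,", nrow(x$pairs),
      "consensus base pairs\nCBC counts:\n")
  print(x$cbc)
  invisible(x)
}

#' Diagnostic CBC positions between two groups
#'
#' Returns the consensus bp ids at which *every* member of group A differs
#' from *every* member of group B by a compensatory base change - the
#' positions that cleanly distinguish two lineages.
#'
#' @param aln A `structured_alignment`.
#' @param pairs Consensus pairs from [consensus_pairs()].
#' @param group_a,group_b Disjoint character vectors of row ids.
#' @return A tibble: `bp_id`, `col5`, `col3`, `helix`.
#' @export
lineage_diagnostic_cbcs <- function(aln, pairs, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups overlap: ", paste(intersect(group_a, group_b),
                                   collapse = ", "), call. = FALSE)
  }
  rows <- aln$rows
  stopifnot(all(c(group_a, group_b) %in% rows$id))
  charmat <- t(vapply(rows$aseq, row_chars, character(aln$n_cols)))
  rownames(charmat) <- rows$id
  diag_ok <- vapply(seq_len(nrow(pairs)), function(k) {
    c5 <- pairs$col5[k]; c3 <- pairs$col3[k]
    all(vapply(group_a, function(a) {
      all(vapply(group_b, function(b) {
        classify_change(c(charmat[a, c5], charmat[a, c3]),
                        c(charmat[b, c5], charmat[b, c3])) == "CBC"
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  pairs[diag_ok, c("bp_id", "col5", "col3", "helix")]
}
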
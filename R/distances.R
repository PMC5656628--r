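#' Complete-deletion p-distance matrix
#'
#' Uncorrected pairwise distances: every alignment column containing a gap
#' or ambiguity code in *any* row is removed once, globally (complete
#' deletion, the MEGA default this package mirrors), and the distance is
#' the fraction of mismatching retained columns. Pairwise deletion (each
#' pair keeps its own comparable columns) is available behind a flag; note
#' that complete deletion is what the reported reference distances assume.
#'
#' @param aln A `structured_alignment`, or a tibble with `id` and `aseq`
#'   columns (gapped rows of equal length).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return An object of class `p_distance`: `taxa`, symmetric matrix `d`
#'   in `[0, 1]`, and `n_sites_used` (retained columns; for pairwise
#'   deletion, the minimum over pairs).
#' @export
p_distance_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  rows <- if (inherits(aln, "structured_alignment")) aln$rows else aln
  stopifnot(all(c("id", "aseq") %in% names(rows)), nrow(rows) >= 2L)
  n_cols <- unique(nchar(rows$aseq))
  stopifnot(length(n_cols) == 1L)
  charmat <- t(vapply(rows$aseq, row_chars, character(n_cols)))
  rownames(charmat) <- rows$id
  good <- charmat %in% c("A", "C", "G", "U")
  dim(good) <- dim(charmat)
  nt <- nrow(charmat)
  d <- matrix(0, nt, nt, dimnames = list(rows$id, rows$id))
  if (deletion == "complete") {
    keep <- apply(good, 2, all)
    if (!any(keep)) stop("no columns retained under complete deletion", call. = FALSE)
    m <- charmat[, keep, drop = FALSE]
    n_used <- sum(keep)
    for (x in seq_len(nt - 1L)) {
      for (y in (x + 1L):nt) {
        d[x, y] <- d[y, x] <- sum(m[x, ] != m[y, ]) / n_used
      }
    }
  } else {
    warning("pairwise deletion selected; reference distances assume complete deletion",
            call. = FALSE)
    n_used <- integer(0)
    for (x in seq_len(nt - 1L)) {
      for (y in (x + 1L):nt) {
        ok <- good[x, ] & good[y, ]
        if (!any(ok)) stop("no comparable columns for pair ", rows$id[x],
                           " / ", rows$id[y], call. = FALSE)
        d[x, y] <- d[y, x] <- sum(charmat[x, ok] != charmat[y, ok]) / sum(ok)
        n_used <- c(n_used, sum(ok))
      }
    }
    n_used <- min(n_used)
  }
  structure(list(taxa = rows$id, d = d, n_sites_used = n_used,
                 deletion = deletion),
            class = "p_distance")
}

#' @export
print.p_distance <- function(x, ...) {
  cat("p-distance matrix (", x$deletion, " deletion, ", x$n_sites_used,
      " sites)\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Between-group distance
#'
#' Mean (or maximum) of the pairwise distances across two disjoint groups
#' of taxa. The unweighted mean over all cross pairs is the usual
#' "distance between lineages"; the maximum is reported for "as high as"
#' style statements.
#'
#' @param dm A `p_distance`.
#' @param g1,g2 Disjoint character vectors of taxon ids.
#' @param stat `"mean"` (default) or `"max"`.
#' @return A single fraction.
#' @export
between_group_distance <- function(dm, g1, g2, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(dm, "p_distance"), length(g1) > 0, length(g2) > 0)
  if (length(intersect(g1, g2)) > 0L) {
    stop("groups overlap: ", paste(intersect(g1, g2), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(c(g1, g2) %in% dm$taxa))
  vals <- dm$d[g1, g2, drop = FALSE]
  if (stat == "mean") mean(vals) else max(vals)
}

#' Within-group distance
#'
#' Mean (or maximum) pairwise distance among the members of one group;
#' zero for singleton groups.
#'
#' @inheritParams between_group_distance
#' @param g Character vector of taxon ids.
#' @export
within_group_distance <- function(dm, g, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(dm, "p_distance"), all(g %in% dm$taxa))
  if (length(g) < 2L) return(0)
  vals <- dm$d[g, g][upper.tri(diag(length(g)))]
  if (stat == "mean") mean(vals) else max(vals)
}

#' Per-column conservation profile of an alignment
#'
#' For every column, the most frequent base among non-gap symbols and its
#' fraction; the consensus symbol is that base when the fraction reaches
#' `threshold` and otherwise the IUPAC code covering all observed bases
#' (majority-rule consensus diagrams use 70% and 60% thresholds).
#'
#' @param aln A `structured_alignment` or tibble with `aseq`.
#' @param threshold Majority threshold in (0, 1]; default 0.7.
#' @return A tibble: `col`, `consensus`, `max_frac`, with the threshold as
#'   an attribute.
#' @export
conservation_profile <- function(aln, threshold = 0.7) {
  rows <- if (inherits(aln, "structured_alignment")) aln$rows else aln
  n_cols <- unique(nchar(rows$aseq))
  charmat <- t(vapply(rows$aseq, row_chars, character(n_cols)))
  iupac <- stats::setNames(names(Biostrings::IUPAC_CODE_MAP),
                           gsub("T", "U", Biostrings::IUPAC_CODE_MAP))
  out <- purrr::map_dfr(seq_len(n_cols), function(cc) {
    col <- charmat[, cc]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      return(tibble::tibble(col = cc, consensus = "-", max_frac = NA_real_))
    }
    tab <- sort(table(col), decreasing = TRUE)
    frac <- tab[1] / length(col)
    cons <- if (frac >= threshold) {
      names(tab)[1]
    } else {
      key <- paste(sort(unique(col)), collapse = "")
      unname(iupac[key] %||% "N")
    }
    tibble::tibble(col = cc, consensus = cons, max_frac = unname(frac))
  })
  attr(out, "threshold") <- threshold
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape) on a `p_distance`, used as the
#' guide tree for progressive alignment and for quick clustering checks;
#' model-based phylogeny inference is out of scope here.
#'
#' @param dm A `p_distance` (at least 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "p_distance"))
  if (length(dm$taxa) < 3L) stop("nj_tree requires >= 3 taxa", call. = FALSE)
  ape::nj(stats::as.dist(dm$d))
}
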
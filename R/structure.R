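#' Parse a Vienna dot-bracket string into a partner table
#'
#' Converts a pseudoknot-free dot-bracket string into an integer vector
#' `partner` with `partner[i]` the 1-based index of the base paired with
#' position `i`, or `NA` if position `i` is unpaired. Only the `.()`
#' alphabet is accepted; bracket layers used for pseudoknots are rejected
#' because ITS2 structures are nested.
#'
#' @param db A single dot-bracket string.
#' @param seq Optional RNA sequence of equal length; if supplied, lengths are
#'   checked and IUPAC-ambiguous residues may not occupy paired positions.
#' @return An integer vector of pairing partners (`NA` = unpaired), of class
#'   `its2_partner`.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(db, seq = NULL) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0L) {
    stop("invalid dot-bracket character '", chars[bad[1]],
         "' at column ", bad[1], call. = FALSE)
  }
  if (!is.null(seq)) {
    res <- seq_residues(seq)
    if (nchar(res) != length(chars)) {
      stop("structure length ", length(chars),
           " does not match sequence length ", nchar(res), call. = FALSE)
    }
  }
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced at column ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced at column ", stack[length(stack)], call. = FALSE)
  }
  if (!is.null(seq)) {
    res <- strsplit(seq_residues(seq), "")[[1]]
    amb <- which(!is.na(partner) & !res %in% c("A", "C", "G", "U"))
    if (length(amb) > 0L) {
      stop("ambiguous residue '", res[amb[1]], "' at paired position ",
           amb[1], "; ambiguity codes must be unpaired", call. = FALSE)
    }
  }
  structure(partner, class = "its2_partner")
}

#' Render a partner table as a dot-bracket string
#'
#' Inverse of [parse_dotbracket()]: `parse_dotbracket(render_dotbracket(p))`
#' is the identity for every valid nested partner table.
#'
#' @param partner Integer partner vector (`NA` = unpaired).
#' @return A dot-bracket string.
#' @export
render_dotbracket <- function(partner) {
  n <- length(partner)
  out <- rep(".", n)
  paired <- which(!is.na(partner))
  out[paired[partner[paired] > paired]] <- "("
  out[paired[partner[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

#' Validate a partner table
#'
#' Checks the structural invariants every secondary structure in the package
#' must satisfy: involution (`partner[partner[i]] == i`), no self-pairing,
#' nestedness (no crossing pairs), and a minimum hairpin loop size.
#'
#' @param partner Integer partner vector.
#' @param min_loop Minimum number of unpaired nucleotides enclosed by any
#'   pair (default 1).
#' @return `partner`, invisibly; errors on violation.
#' @export
validate_structure <- function(partner, min_loop = 1L) {
  paired <- which(!is.na(partner))
  if (length(paired) == 0L) return(invisible(partner))
  p <- partner[paired]
  if (any(p < 1L | p > length(partner), na.rm = TRUE)) {
    stop("partner index out of range", call. = FALSE)
  }
  if (anyNA(partner[p]) || any(partner[p] != paired)) {
    stop("partner table is not an involution", call. = FALSE)
  }
  if (any(p == paired)) stop("self-pairing is not allowed", call. = FALSE)
  op <- paired[p > paired]
  cl <- partner[op]
  if (any(cl - op - 1L < min_loop)) {
    stop("hairpin loop shorter than min_loop = ", min_loop, call. = FALSE)
  }
  # nestedness: for pairs (i,j) sorted by i, no (i<k<j<l)
  if (length(op) > 1L) {
    ord <- order(op)
    io <- op[ord]; jo <- cl[ord]
    # a stack-free check: for consecutive opens, each must be nested or disjoint
    stack <- integer(0)
    for (t in seq_along(io)) {
      while (length(stack) > 0L && stack[length(stack)] < io[t]) {
        stack <- stack[-length(stack)]
      }
      if (length(stack) > 0L && jo[t] > stack[length(stack)]) {
        stop("crossing pairs (pseudoknot) detected", call. = FALSE)
      }
      stack <- c(stack, jo[t])
    }
  }
  invisible(partner)
}

#' List the base pairs of a structure
#'
#' @param partner Integer partner vector.
#' @return A tibble with columns `i`, `j` (1-based, `i < j`).
#' @export
structure_pairs <- function(partner) {
  i <- which(!is.na(partner) & partner > seq_along(partner))
  tibble::tibble(i = i, j = partner[i])
}

# ---- internal helpers ------------------------------------------------------

seq_residues <- function(seq) {
  if (is.list(seq) && !is.null(seq$seq)) seq$seq else as.character(seq)
}

partner_from_pairs <- function(n, i, j) {
  partner <- rep(NA_integer_, n)
  partner[i] <- as.integer(j)
  partner[j] <- as.integer(i)
  partner
}

# random nested structure on n positions (test/property helper)
random_structure <- function(n, min_loop = 3L, p_pair = 0.6) {
  partner <- rep(NA_integer_, n)
  rec <- function(lo, hi) {
    while (lo <= hi) {
      if (hi - lo >= min_loop + 1L && stats::runif(1) < p_pair) {
        cand <- seq(lo + min_loop + 1L, hi)
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        partner[lo] <<- j
        partner[j] <<- lo
        rec(lo + 1L, j - 1L)
        lo <- j + 1L
      } else {
        lo <- lo + 1L
      }
    }
  }
  rec(1L, n)
  partner
}
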
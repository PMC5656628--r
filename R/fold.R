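#' Folding parameters
#'
#' Parameters of the weighted base-pair maximization folder. Pair weights
#' default to GC = 3, AU = 2, GU = 1, reflecting relative pair stability;
#' allowed pairs are Watson-Crick plus wobble. `min_loop` is the minimum
#' number of unpaired nucleotides a hairpin loop must enclose.
#'
#' @param pair_scores Named numeric vector with elements `GC`, `AU`, `GU`;
#'   a weight of 0 disables that pair type.
#' @param min_loop Minimum hairpin loop length (nt), default 3.
#' @param subopt_delta Score window for near-optimal candidate enumeration.
#' @param max_candidates Maximum number of candidates returned.
#' @param forbid_lonely_pairs If `TRUE` (default), isolated base pairs are
#'   stripped from candidates before ranking; lonely pairs produce spurious
#'   one-pair "helices" that derail hallmark annotation.
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(pair_scores = c(GC = 3, AU = 2, GU = 1),
                        min_loop = 3L, subopt_delta = 2,
                        max_candidates = 20L, forbid_lonely_pairs = TRUE) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_scores)),
            all(pair_scores >= 0), min_loop >= 1L, max_candidates >= 1L,
            subopt_delta >= 0)
  structure(list(pair_scores = pair_scores, min_loop = as.integer(min_loop),
                 subopt_delta = subopt_delta,
                 max_candidates = as.integer(max_candidates),
                 forbid_lonely_pairs = isTRUE(forbid_lonely_pairs)),
            class = "fold_params")
}

encode_bases <- function(seq) {
  chars <- strsplit(toupper(seq_residues(seq)), "")[[1]]
  match(chars, c("A", "C", "G", "U")) - 1L  # NA -> -1 below
}

pair_score_vec <- function(a, b, w) {
  # a, b: single encoded bases (0..3 or NA)
  if (is.na(a) || is.na(b)) return(0)
  key <- paste0(c("A", "C", "G", "U")[a + 1L], c("A", "C", "G", "U")[b + 1L])
  switch(key, AU = , UA = w[["AU"]], GC = , CG = w[["GC"]],
         GU = , UG = w[["GU"]], 0)
}

fill_matrix <- function(enc, params) {
  enc2 <- enc
  enc2[is.na(enc2)] <- -1L
  w <- as.integer(params$pair_scores[c("AU", "GC", "GU")])
  nussinov_fill_cpp(enc2, w, params$min_loop)
}

#' Predict the optimal nested secondary structure of one sequence
#'
#' Maximizes the total weighted pair score over all pseudoknot-free
#' structures using the classic interval dynamic program, with deterministic
#' traceback (the 5'-most base of every open interval is paired with the
#' smallest admissible partner). IUPAC-ambiguous residues never pair.
#'
#' @param seq An RNA sequence (string) or a one-row record with a `seq`
#'   field.
#' @param params A [fold_params()] object.
#' @return A list with `db` (dot-bracket string), `partner` and `score`.
#' @examples
#' fold_optimal("GGGAAACCC")
#' @export
fold_optimal <- function(seq, params = fold_params()) {
  res <- seq_residues(seq)
  n <- nchar(res)
  enc <- encode_bases(res)
  if (n < params$min_loop + 2L) {
    warning("sequence shorter than min_loop + 2; returning all-unpaired",
            call. = FALSE)
    return(list(db = strrep(".", n), partner = rep(NA_integer_, n), score = 0))
  }
  V <- fill_matrix(enc, params)
  partner <- traceback_smallest(enc, V, params)
  if (params$forbid_lonely_pairs) partner <- strip_lonely_pairs(partner)
  list(db = render_dotbracket(partner), partner = partner,
       score = score_structure(enc, partner, params))
}

traceback_smallest <- function(enc, V, params) {
  n <- length(enc)
  w <- params$pair_scores
  partner <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  sc <- function(i, j) pair_score_vec(enc[i], enc[j], w)
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j) {
      if (V[i, j] == 0) break
      paired <- FALSE
      if (i + params$min_loop + 1L > j) break
      for (k in seq(i + params$min_loop + 1L, j)) {
        s <- sc(i, k)
        if (s == 0) next
        inner <- if (k - 1L >= i + 1L) V[i + 1L, k - 1L] else 0
        outer <- if (k + 1L <= j) V[k + 1L, j] else 0
        if (s + inner + outer == V[i, j]) {
          partner[i] <- k; partner[k] <- i
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          i <- i + 1L; j <- k - 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  partner
}

score_structure <- function(enc, partner, params) {
  i <- which(!is.na(partner) & partner > seq_along(partner))
  if (length(i) == 0L) return(0)
  sum(vapply(i, function(ii) pair_score_vec(enc[ii], enc[partner[ii]],
                                            params$pair_scores), numeric(1)))
}

# iteratively remove base pairs with no stacked neighbour (helix length 1)
strip_lonely_pairs <- function(partner) {
  repeat {
    i <- which(!is.na(partner) & partner > seq_along(partner))
    if (length(i) == 0L) return(partner)
    j <- partner[i]
    has_inner <- !is.na(partner[pmin(i + 1L, length(partner))]) &
      partner[pmin(i + 1L, length(partner))] == j - 1L
    has_outer <- i > 1L & j < length(partner)
    has_outer[has_outer] <- {
      ii <- i[has_outer]; jj <- j[has_outer]
      !is.na(partner[ii - 1L]) & partner[ii - 1L] == jj + 1L
    }
    lonely <- !(has_inner | has_outer)
    if (!any(lonely)) return(partner)
    drop <- c(i[lonely], j[lonely])
    partner[drop] <- NA_integer_
  }
}

#' Enumerate near-optimal structures
#'
#' Exhaustively enumerates (Wuchty-style, via the unambiguous
#' first-position decomposition) every nested structure whose score is
#' within `subopt_delta` of the optimum, then ranks candidates by score
#' (descending) with lexicographic dot-bracket order breaking ties. When
#' `forbid_lonely_pairs` is set, isolated pairs are stripped from each
#' candidate before deduplication and ranking.
#'
#' @inheritParams fold_optimal
#' @param max_enum Internal cap on enumerated structures (guards against
#'   combinatorial blow-up on low-information sequences).
#' @return A tibble with columns `db`, `score`, `rank`.
#' @export
enumerate_suboptimal <- function(seq, params = fold_params(),
                                 max_enum = 2000L) {
  res <- seq_residues(seq)
  n <- nchar(res)
  enc <- encode_bases(res)
  if (n < params$min_loop + 2L) {
    return(tibble::tibble(db = strrep(".", n), score = 0, rank = 1L))
  }
  V <- fill_matrix(enc, params)
  opt <- V[1L, n]
  thresh <- opt - params$subopt_delta
  w <- params$pair_scores
  sc <- function(i, j) pair_score_vec(enc[i], enc[j], w)

  done <- list()
  expansions <- 0L
  max_expansions <- 100L * max_enum
  # state: list(intervals = list of c(i,j), pairs = 2-col matrix, base = score)
  stack <- list(list(iv = list(c(1L, n)), pairs = NULL, base = 0))
  while (length(stack) > 0L && length(done) < max_enum &&
         expansions < max_expansions) {
    expansions <- expansions + 1L
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(st$iv) == 0L) {
      done[[length(done) + 1L]] <- st
      next
    }
    iv <- st$iv[[length(st$iv)]]
    rest <- st$iv[-length(st$iv)]
    i <- iv[1]; j <- iv[2]
    rest_bound <- sum(vapply(rest, function(r) V[r[1], r[2]], numeric(1)))
    if (i >= j) {
      # interval closed with no further pairs possible
      stack[[length(stack) + 1L]] <- list(iv = rest, pairs = st$pairs,
                                          base = st$base)
      next
    }
    # option: i unpaired
    ub <- st$base + (if (i + 1L <= j) V[i + 1L, j] else 0) + rest_bound
    if (ub >= thresh) {
      niv <- if (i + 1L <= j) c(rest, list(c(i + 1L, j))) else rest
      stack[[length(stack) + 1L]] <- list(iv = niv, pairs = st$pairs,
                                          base = st$base)
    }
    # options: i paired with k
    if (i + params$min_loop + 1L > j) next
    for (k in seq(i + params$min_loop + 1L, j)) {
      s <- sc(i, k)
      if (s == 0) next
      inner <- if (k - 1L >= i + 1L) V[i + 1L, k - 1L] else 0
      outer <- if (k + 1L <= j) V[k + 1L, j] else 0
      if (st$base + s + inner + outer + rest_bound < thresh) next
      niv <- rest
      if (i + 1L <= k - 1L) niv <- c(niv, list(c(i + 1L, k - 1L)))
      if (k + 1L <= j) niv <- c(niv, list(c(k + 1L, j)))
      stack[[length(stack) + 1L]] <- list(iv = niv,
                                          pairs = rbind(st$pairs, c(i, k)),
                                          base = st$base + s)
    }
  }
  cands <- purrr::map(done, function(st) {
    partner <- rep(NA_integer_, n)
    if (!is.null(st$pairs)) {
      partner <- partner_from_pairs(n, st$pairs[, 1], st$pairs[, 2])
    }
    if (params$forbid_lonely_pairs) partner <- strip_lonely_pairs(partner)
    list(db = render_dotbracket(partner),
         score = score_structure(enc, partner, params))
  })
  # the capped enumeration may stop before reaching the optimum; the
  # deterministic optimal traceback is always a candidate
  opt_partner <- traceback_smallest(enc, V, params)
  if (params$forbid_lonely_pairs) opt_partner <- strip_lonely_pairs(opt_partner)
  cands[[length(cands) + 1L]] <- list(
    db = render_dotbracket(opt_partner),
    score = score_structure(enc, opt_partner, params))
  out <- tibble::tibble(
    db = purrr::map_chr(cands, "db"),
    score = purrr::map_dbl(cands, "score")
  )
  out <- dplyr::distinct(out, .data$db, .keep_all = TRUE)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$db)
  out <- dplyr::filter(out, .data$score >= max(.data$score) - params$subopt_delta)
  out <- utils::head(out, params$max_candidates)
  out$rank <- seq_len(nrow(out))
  out
}

#' Brute-force folding oracle
#'
#' Exhaustively enumerates every pseudoknot-free structure of a short
#' sequence (at most 16 nt) and returns the optimal score together with all
#' co-optimal structures. Used as an independent oracle for the dynamic
#' program; it shares no code with [fold_optimal()]'s fill.
#'
#' @inheritParams fold_optimal
#' @return A list with `score` and `structures` (character vector of
#'   dot-bracket strings).
#' @export
brute_force_fold <- function(seq, params = fold_params()) {
  res <- seq_residues(seq)
  n <- nchar(res)
  if (n > 16L) stop("brute_force_fold is guarded to length <= 16", call. = FALSE)
  enc <- encode_bases(res)
  enc[is.na(enc)] <- -1L
  w <- as.integer(params$pair_scores[c("AU", "GC", "GU")])
  out <- brute_force_cpp(enc, w, params$min_loop)
  list(score = out$score, structures = out$structures)
}

#' Fold every record of a sequence table
#'
#' Tibble-level wrapper: enumerates near-optimal candidates for each
#' sequence and stores them in a list-column.
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param params A [fold_params()] object.
#' @return `records` with an added list-column `candidates` (each a tibble
#'   `db`, `score`, `rank`).
#' @param max_enum Internal enumeration cap passed to
#'   [enumerate_suboptimal()].
#' @export
fold_sequences <- function(records, params = fold_params(),
                           max_enum = 2000L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  records$candidates <- purrr::map(records$seq, enumerate_suboptimal,
                                   params = params, max_enum = max_enum)
  records
}
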
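#' Hallmark-check configuration
#'
#' Expected features of the eukaryote/Chlorophyta ITS2 consensus used to
#' select and validate structures: the four-helix topology, the
#' pyrimidine-pyrimidine mismatch in helix II, the YRRY motif on the 5' side
#' of helix III, and fixed spacer lengths between helices I-II and II-III.
#' The per-helix conserved first-two-base-pair identities and exact spacer
#' lengths vary across lineages, so they are configuration, not constants;
#' the defaults match the consensus shipped with the synthetic generator.
#'
#' @param expected_spacers Named integer vector with elements `I_II` and
#'   `II_III`: expected spacer lengths (nt) between those helices.
#' @param weights Named numeric vector of hallmark score weights:
#'   `topology` (all four helices present), `yy`, `yrry`, `spacer` (per
#'   spacer of correct length).
#' @param bulge_tol Maximum unpaired nucleotides on each side of an internal
#'   loop for two stacked runs to count as one helix (default 2).
#' @return A list of class `hallmark_config`.
#' @export
hallmark_config <- function(expected_spacers = c(I_II = 3L, II_III = 4L),
                            weights = c(topology = 4, yy = 2, yrry = 2,
                                        spacer = 1),
                            bulge_tol = 2L) {
  structure(list(expected_spacers = expected_spacers, weights = weights,
                 bulge_tol = as.integer(bulge_tol)),
            class = "hallmark_config")
}

#' Identify and label the ITS2 helices of a structure
#'
#' Groups base pairs into helices (maximal stacked runs, merging across
#' internal loops with at most `bulge_tol` unpaired nucleotides per side),
#' determines the nesting hierarchy, labels the four longest root-level
#' helices I-IV in 5' to 3' order, labels the 5'-most helix branching off
#' helix III as IIIa, and computes the spacer lengths between consecutive
#' labeled helices. Fewer than four root-level helices is not an error: the
#' annotation is returned with the missing labels flagged.
#'
#' @param partner Integer partner vector (or dot-bracket string).
#' @param config A [hallmark_config()].
#' @return A list of class `helix_annotation` with elements `helices` (a
#'   tibble: `label`, `arm5_start`, `arm5_end`, `arm3_start`, `arm3_end`,
#'   `n_pairs`, `parent`, and a `pairs` list-column), `spacers` (named
#'   integer vector), `n` (sequence length) and `complete` (all of I-IV
#'   found).
#' @export
annotate_helices <- function(partner, config = hallmark_config()) {
  if (is.character(partner)) partner <- parse_dotbracket(partner)
  n <- length(partner)
  pr <- structure_pairs(partner)
  if (nrow(pr) == 0L) {
    return(structure(list(
      helices = tibble::tibble(label = character(), arm5_start = integer(),
                               arm5_end = integer(), arm3_start = integer(),
                               arm3_end = integer(), n_pairs = integer(),
                               parent = integer(), pairs = list()),
      spacers = c(B9_I = NA_integer_, I_II = NA_integer_, II_III = NA_integer_,
                  III_IV = NA_integer_, IV_B9 = NA_integer_),
      n = n, complete = FALSE), class = "helix_annotation"))
  }
  pr <- dplyr::arrange(pr, .data$i)
  tol <- config$bulge_tol
  hid <- integer(nrow(pr))
  hid[1] <- 1L
  if (nrow(pr) > 1L) {
    for (t in 2:nrow(pr)) {
      p <- pr[t - 1L, ]; q <- pr[t, ]
      nested <- q$i > p$i && q$j < p$j
      if (nested && (q$i - p$i - 1L) <= tol && (p$j - q$j - 1L) <= tol) {
        hid[t] <- hid[t - 1L]
      } else {
        hid[t] <- max(hid) + 1L
      }
    }
  }
  helices <- purrr::map_dfr(split(pr, hid), function(g) {
    tibble::tibble(arm5_start = min(g$i), arm5_end = max(g$i),
                   arm3_start = min(g$j), arm3_end = max(g$j),
                   n_pairs = nrow(g), pairs = list(g))
  })
  # parent: tightest enclosing helix (by outermost pair)
  helices$parent <- vapply(seq_len(nrow(helices)), function(k) {
    i0 <- helices$arm5_start[k]; j0 <- helices$arm3_end[k]
    enc <- which(helices$arm5_start < i0 & helices$arm3_end > j0)
    if (length(enc) == 0L) return(NA_integer_)
    enc[which.max(helices$arm5_start[enc])]
  }, integer(1))
  helices$label <- NA_character_
  root <- which(is.na(helices$parent))
  take <- root[order(-helices$n_pairs[root], helices$arm5_start[root])]
  take <- sort(utils::head(take, 4L))  # 5'->3' order of the chosen helices
  helices$label[take] <- c("I", "II", "III", "IV")[seq_along(take)]
  # IIIa: 5'-most child of helix III
  h3 <- which(helices$label %in% "III")
  if (length(h3) == 1L) {
    kids <- which(!is.na(helices$parent) & helices$parent == h3)
    if (length(kids) > 0L) {
      helices$label[kids[which.min(helices$arm5_start[kids])]] <- "IIIa"
    }
  }
  lab <- function(l) {
    k <- which(helices$label %in% l)
    if (length(k) == 1L) helices[k, ] else NULL
  }
  sp <- c(B9_I = NA_integer_, I_II = NA_integer_, II_III = NA_integer_,
          III_IV = NA_integer_, IV_B9 = NA_integer_)
  hI <- lab("I"); hII <- lab("II"); hIII <- lab("III"); hIV <- lab("IV")
  if (!is.null(hI)) sp["B9_I"] <- hI$arm5_start - 1L
  if (!is.null(hI) && !is.null(hII)) sp["I_II"] <- hII$arm5_start - hI$arm3_end - 1L
  if (!is.null(hII) && !is.null(hIII)) sp["II_III"] <- hIII$arm5_start - hII$arm3_end - 1L
  if (!is.null(hIII) && !is.null(hIV)) sp["III_IV"] <- hIV$arm5_start - hIII$arm3_end - 1L
  if (!is.null(hIV)) sp["IV_B9"] <- n - hIV$arm3_end
  helices <- dplyr::select(helices, "label", "arm5_start", "arm5_end",
                           "arm3_start", "arm3_end", "n_pairs", "parent",
                           "pairs")
  structure(list(helices = helices, spacers = sp, n = n,
                 complete = all(c("I", "II", "III", "IV") %in% helices$label)),
            class = "helix_annotation")
}

#' Score a structure against the ITS2 hallmarks
#'
#' Locates the pyrimidine-pyrimidine internal mismatch in helix II and the
#' YRRY motif on the 5' arm of helix III (reporting the actual bases, e.g.
#' UGGU or UAAU), checks the helix I-II and II-III spacer lengths against
#' the configured expectations, records the first two base pairs of helices
#' I-III, checks (but never scores) the AGG motif at the base of helix IV,
#' and aggregates everything into a deterministic score used for candidate
#' selection. Absent features simply score 0.
#'
#' @param annotation A [annotate_helices()] result.
#' @param seq The RNA sequence the structure belongs to.
#' @param config A [hallmark_config()].
#' @return A list of class `hallmark_report`: `yy`, `yrry`, `spacer_ok`,
#'   `first_two_bp`, `agg_motif_found`, `agg_score`.
#' @export
check_hallmarks <- function(annotation, seq, config = hallmark_config()) {
  stopifnot(inherits(annotation, "helix_annotation"))
  res <- strsplit(seq_residues(seq), "")[[1]]
  hel <- annotation$helices
  lab <- function(l) {
    k <- which(hel$label %in% l)
    if (length(k) == 1L) hel[k, ] else NULL
  }
  yy <- list(found = FALSE, bases = c(NA_character_, NA_character_),
             position = c(NA_integer_, NA_integer_))
  hII <- lab("II")
  if (!is.null(hII)) {
    p <- dplyr::arrange(hII$pairs[[1]], .data$i)
    if (nrow(p) > 1L) {
      for (t in seq_len(nrow(p) - 1L)) {
        # 1x1 internal loop between stacked pairs t and t+1
        if (p$i[t + 1L] - p$i[t] == 2L && p$j[t] - p$j[t + 1L] == 2L) {
          b5 <- res[p$i[t] + 1L]; b3 <- res[p$j[t] - 1L]
          if (b5 %in% PYRIMIDINES && b3 %in% PYRIMIDINES) {
            yy <- list(found = TRUE, bases = c(b5, b3),
                       position = c(p$i[t] + 1L, p$j[t] - 1L))
            break
          }
        }
      }
    }
  }
  yrry <- list(found = FALSE, motif = NA_character_, position = NA_integer_)
  hIII <- lab("III")
  if (!is.null(hIII)) {
    arm <- seq(hIII$arm5_start, hIII$arm5_end)
    if (length(arm) >= 4L) {
      for (s in seq_len(length(arm) - 3L)) {
        win <- res[arm[s:(s + 3L)]]
        if (win[1] %in% PYRIMIDINES && win[2] %in% PURINES &&
            win[3] %in% PURINES && win[4] %in% PYRIMIDINES) {
          yrry <- list(found = TRUE, motif = paste(win, collapse = ""),
                       position = arm[s])
          break
        }
      }
    }
  }
  exp_sp <- config$expected_spacers
  spacer_ok <- c(
    I_II = isTRUE(annotation$spacers[["I_II"]] == exp_sp[["I_II"]]),
    II_III = isTRUE(annotation$spacers[["II_III"]] == exp_sp[["II_III"]])
  )
  first_two <- purrr::map(c(I = "I", II = "II", III = "III"), function(l) {
    h <- lab(l)
    if (is.null(h)) return(character(0))
    p <- dplyr::arrange(h$pairs[[1]], .data$i)
    p <- utils::head(p, 2L)
    paste0(res[p$i], res[p$j])
  })
  agg_motif <- FALSE
  hIV <- lab("IV")
  if (!is.null(hIV) && hIV$arm5_start > 3L) {
    agg_motif <- paste(res[(hIV$arm5_start - 3L):(hIV$arm5_start - 1L)],
                       collapse = "") == "AGG"
  }
  w <- config$weights
  agg_score <- w[["topology"]] * annotation$complete +
    w[["yy"]] * yy$found + w[["yrry"]] * yrry$found +
    w[["spacer"]] * sum(spacer_ok)
  structure(list(yy = yy, yrry = yrry, spacer_ok = spacer_ok,
                 first_two_bp = first_two, agg_motif_found = agg_motif,
                 agg_score = unname(agg_score)),
            class = "hallmark_report")
}

#' Select the hallmark-best structure among folding candidates
#'
#' The preliminary structure of each sequence is chosen among the
#' near-optimal folding candidates by hallmark score, with fold score and
#' then candidate rank breaking ties - mirroring hallmark-guided selection
#' rather than pure energy minimization.
#'
#' @param candidates Tibble of candidates (`db`, `score`, `rank`) from
#'   [enumerate_suboptimal()].
#' @param seq The RNA sequence.
#' @param config A [hallmark_config()].
#' @return A list: `db`, `partner`, `score`, `annotation`, `report`.
#' @export
select_structure <- function(candidates, seq, config = hallmark_config()) {
  stopifnot(nrow(candidates) >= 1L)
  scored <- purrr::pmap(candidates, function(db, score, rank, ...) {
    partner <- parse_dotbracket(db)
    ann <- annotate_helices(partner, config)
    rep <- check_hallmarks(ann, seq, config)
    list(db = db, partner = partner, score = score, rank = rank,
         annotation = ann, report = rep)
  })
  agg <- purrr::map_dbl(scored, ~ .x$report$agg_score)
  fold <- purrr::map_dbl(scored, "score")
  rank <- purrr::map_dbl(scored, "rank")
  ord <- order(-agg, -fold, rank)
  scored[[ord[1]]]
}

#' Transfer a reference structure onto a homologous sequence
#'
#' Homology modeling of a secondary structure, the approach used by
#' template-based ITS2 structure annotation: the reference sequence is
#' globally aligned to the target and every reference base pair whose two
#' positions map to non-gap target positions forming a canonical pair is
#' transferred. The target keeps its own bases; only the pairing
#' hypothesis is borrowed.
#'
#' @param ref_seq,ref_db Reference sequence and dot-bracket structure.
#' @param seq Target sequence.
#' @return A dot-bracket string for `seq`.
#' @export
structure_by_homology <- function(ref_seq, ref_db, seq) {
  map <- homology_map(ref_seq, seq)
  partner_ref <- parse_dotbracket(ref_db)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  pr <- structure_pairs(partner_ref)
  for (k in seq_len(nrow(pr))) {
    ti <- map[pr$i[k]]; tj <- map[pr$j[k]]
    if (!is.na(ti) && !is.na(tj) &&
        chars[ti] %in% c("A", "C", "G", "U") &&
        chars[tj] %in% c("A", "C", "G", "U") &&
        is_valid_pair(chars[ti], chars[tj])) {
      partner[ti] <- tj
      partner[tj] <- ti
    }
  }
  render_dotbracket(partner)
}

# position map from sequence a to sequence b via global pairwise alignment
homology_map <- function(seq_a, seq_b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -1, baseOnly = FALSE, type = "RNA")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(seq_a), Biostrings::RNAString(seq_b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 3, gapExtension = 1)
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  a_pos <- cumsum(ga != "-")
  b_pos <- cumsum(gb != "-")
  map <- rep(NA_integer_, nchar(seq_a))
  ok <- ga != "-" & gb != "-"
  map[a_pos[ok]] <- b_pos[ok]
  map
}

# consensus structure over the individual folds: every strain's folded pairs
# are mapped onto a scaffold sequence and pairs supported by at least
# min_support of the strains are kept (highest support first, crossers
# dropped). Misfolds are idiosyncratic while the shared architecture is
# folded correctly in most strains, so the vote recovers the common
# topology.
consensus_fold_reference <- function(seqs, dbs, scaffold_idx,
                                     min_support = 0.5) {
  n <- length(seqs)
  scaffold <- seqs[[scaffold_idx]]
  tal <- list()
  for (k in seq_len(n)) {
    map <- if (k == scaffold_idx) seq_len(nchar(scaffold)) else
      homology_map(seqs[[k]], scaffold)
    pr <- structure_pairs(parse_dotbracket(dbs[[k]]))
    i <- map[pr$i]; j <- map[pr$j]
    keep <- !is.na(i) & !is.na(j)
    tal[[k]] <- tibble::tibble(i = i[keep], j = j[keep])
  }
  tal <- dplyr::count(dplyr::bind_rows(tal), .data$i, .data$j)
  tal <- dplyr::filter(tal, .data$n >= min_support * n)
  tal <- dplyr::arrange(tal, dplyr::desc(.data$n), .data$i)
  chars <- strsplit(toupper(scaffold), "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  for (k in seq_len(nrow(tal))) {
    i <- tal$i[k]; j <- tal$j[k]
    if (!is.na(partner[i]) || !is.na(partner[j])) next
    if (!chars[i] %in% c("A", "C", "G", "U") ||
        !chars[j] %in% c("A", "C", "G", "U") ||
        !is_valid_pair(chars[i], chars[j])) next
    op <- which(!is.na(partner) & partner > seq_along(partner))
    crosses <- any((op < i & partner[op] > i & partner[op] < j) |
                     (op > i & op < j & partner[op] > j))
    if (crosses) next
    partner[i] <- j
    partner[j] <- i
  }
  render_dotbracket(partner)
}

#' Fold and hallmark-annotate every record of a sequence table
#'
#' Tibble-level wrapper combining [fold_sequences()], [select_structure()]
#' and [structure_by_homology()]: every sequence is folded and its
#' hallmark-best candidate selected; a consensus structure is then voted
#' from all individual folds (pairs supported by most strains) and
#' transferred to each strain, the transfer being adopted wherever it
#' scores at least as well on the hallmarks as the strain's own fold.
#' This mirrors practice for ITS2: preliminary structures are chosen by
#' hallmarks and by comparative analysis of the other structures found in
#' the dataset, because folding individual sequences is unreliable.
#' Set `transfer = FALSE` for independent per-sequence folds.
#'
#' @param records Tibble with columns `id`, `seq`.
#' @param fold_params A [fold_params()].
#' @param config A [hallmark_config()].
#' @param transfer Vote a consensus reference from the individual folds and
#'   transfer it by homology (default TRUE).
#' @param max_enum Per-sequence enumeration cap (kept small here: the
#'   comparative transfer phase, not deep enumeration, provides the
#'   alternative structures).
#' @return `records` with added columns `db`, `fold_score`, `agg_score`,
#'   `yy`, `yrry`, `structure_method` (`"fold"` or `"homology"`), and
#'   list-columns `annotation`, `report`.
#' @export
predict_structures <- function(records, fold_params = its2cbc::fold_params(),
                               config = hallmark_config(), transfer = TRUE,
                               max_enum = 20L) {
  if (!"candidates" %in% names(records)) {
    records <- fold_sequences(records, fold_params, max_enum = max_enum)
  }
  sel <- purrr::map2(records$candidates, records$seq, function(cands, s) {
    select_structure(cands, s, config)
  })
  db <- purrr::map_chr(sel, "db")
  agg <- purrr::map_dbl(sel, ~ .x$report$agg_score)
  fold <- purrr::map_dbl(sel, "score")
  method <- rep("fold", nrow(records))
  if (transfer && nrow(records) > 1L) {
    scaffold <- order(-agg, -fold)[1]
    ref_db <- consensus_fold_reference(records$seq, db, scaffold)
    ref_seq <- records$seq[[scaffold]]
    for (k in seq_len(nrow(records))) {
      tdb <- if (k == scaffold) ref_db else
        structure_by_homology(ref_seq, ref_db, records$seq[[k]])
      tp <- parse_dotbracket(tdb)
      tagg <- check_hallmarks(annotate_helices(tp, config), records$seq[[k]],
                              config)$agg_score
      if (tagg >= agg[k] && tdb != db[k]) {
        db[k] <- tdb
        agg[k] <- tagg
        fold[k] <- score_structure(encode_bases(records$seq[[k]]), tp,
                                   fold_params)
        method[k] <- "homology"
      }
    }
  }
  ann <- purrr::map2(db, records$seq,
                     ~ annotate_helices(parse_dotbracket(.x), config))
  rep <- purrr::pmap(list(ann, records$seq), check_hallmarks, config = config)
  records$db <- db
  records$fold_score <- fold
  records$agg_score <- purrr::map_dbl(rep, "agg_score")
  records$yy <- purrr::map_chr(rep, ~ paste(.x$yy$bases, collapse = "x"))
  records$yrry <- purrr::map_chr(rep, ~ .x$yrry$motif %||% NA_character_)
  records$structure_method <- method
  records$annotation <- ann
  records$report <- rep
  records
}
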
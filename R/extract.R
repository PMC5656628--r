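# Default flank motifs: approximations to the conserved 3' end of the
# Viridiplantae 5.8S rRNA and 5' start of the 28S rRNA. The profile models
# used by full HMM-based ITS2 boundary annotators are not public in a form
# this package can ship, so these PWM consensi are stand-ins tuned to
# conserved flanks; override them via flank_model() for other taxa.
DEFAULT_MOTIF_5P <- "GAACGCACAUUGGGUGGCAU"
DEFAULT_MOTIF_3P <- "AUGCCACCACCUCACGGGAA"

#' Flank model for ITS2 boundary annotation
#'
#' Describes the conserved motifs flanking ITS2: the 3' end of the 5.8S
#' rRNA and the 5' start of the 28S rRNA. Scanning is mismatch-counting
#' over a window from each sequence end; profile-HMM boundary annotation is
#' deliberately replaced by this PWM scan, which behaves identically on
#' well-conserved flanks.
#'
#' @param motif_5p,motif_3p Motif strings (IUPAC allowed).
#' @param max_mismatch Maximum mismatches for a hit (default 3).
#' @param search_window Number of nucleotides from each sequence end to
#'   scan (default 60).
#' @return A list of class `flank_model`.
#' @export
flank_model <- function(motif_5p = DEFAULT_MOTIF_5P,
                        motif_3p = DEFAULT_MOTIF_3P,
                        max_mismatch = 3L, search_window = 60L) {
  stopifnot(nchar(motif_5p) > 0, nchar(motif_3p) > 0, max_mismatch >= 0)
  structure(list(motif_5p = toupper(motif_5p), motif_3p = toupper(motif_3p),
                 max_mismatch = as.integer(max_mismatch),
                 search_window = as.integer(search_window)),
            class = "flank_model")
}

# IUPAC codes as base bitmasks (A=1, C=2, G=4, U=8); two symbols are
# compatible when their masks intersect
iupac_bits <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  bits <- vapply(map, function(x) {
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[strsplit(x, "")[[1]]])
  }, integer(1))
  names(bits) <- gsub("T", "U", names(bits))
  bits
})

motif_hits <- function(seq_chars, motif, starts, max_mismatch) {
  mbits <- unname(iupac_bits[strsplit(motif, "", fixed = TRUE)[[1]]])
  sbits <- unname(iupac_bits[seq_chars])
  sbits[is.na(sbits)] <- 0L
  L <- length(mbits)
  mism <- vapply(starts, function(s) {
    sum(bitwAnd(sbits[s:(s + L - 1L)], mbits) == 0L)
  }, integer(1))
  out <- tibble::tibble(start = starts, end = starts + L - 1L,
                        mismatches = mism, score = L - mism)
  dplyr::filter(out, .data$mismatches <= max_mismatch)
}

#' Locate the ITS2 boundaries inside an amplicon
#'
#' Scans for the 5.8S 3'-end motif within `search_window` nt of the 5' end
#' and the 28S 5'-start motif within `search_window` nt of the 3' end. The
#' ITS2 is the region strictly between the best hits. Among equal-scoring
#' hits, the pair maximizing the resulting B9 stem length wins, then the
#' 5'-most; the B9 structural motif is required for precise ITS2 excision,
#' so it arbitrates boundary ties.
#'
#' @param amplicon RNA sequence string (5.8S-ITS2-28S fragment).
#' @param model A [flank_model()].
#' @return A list: `its2_start`, `its2_end` (1-based, inclusive), `flank5`,
#'   `flank3` (the flanking subsequences), `b9` (see [build_b9()]).
#' @export
locate_flanks <- function(amplicon, model = flank_model()) {
  res <- toupper(seq_residues(amplicon))
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  n <- length(chars)
  L5 <- nchar(model$motif_5p); L3 <- nchar(model$motif_3p)
  if (n <= L5 + L3) {
    stop("amplicon shorter than the two flank motifs combined", call. = FALSE)
  }
  starts5 <- seq_len(min(model$search_window, n - L5 + 1L))
  hits5 <- motif_hits(chars, model$motif_5p, starts5, model$max_mismatch)
  if (nrow(hits5) == 0L) stop("5' boundary not found", call. = FALSE)
  starts3 <- seq(max(1L, n - L3 + 1L - model$search_window + 1L), n - L3 + 1L)
  hits3 <- motif_hits(chars, model$motif_3p, starts3, model$max_mismatch)
  if (nrow(hits3) == 0L) stop("3' boundary not found", call. = FALSE)
  best5 <- dplyr::filter(hits5, .data$score == max(.data$score))
  best3 <- dplyr::filter(hits3, .data$score == max(.data$score))
  combos <- tidyr::expand_grid(e5 = best5$end, s3 = best3$start)
  combos <- dplyr::filter(combos, .data$s3 > .data$e5 + 1L)
  if (nrow(combos) == 0L) stop("flank hits leave no ITS2 between them", call. = FALSE)
  combos$b9_len <- purrr::map2_int(combos$e5, combos$s3, function(e5, s3) {
    suppressWarnings(build_b9(substr(res, 1L, e5), substr(res, s3, n))$length)
  })
  combos <- dplyr::arrange(combos, dplyr::desc(.data$b9_len), .data$e5, .data$s3)
  e5 <- combos$e5[1]; s3 <- combos$s3[1]
  flank5 <- substr(res, 1L, e5)
  flank3 <- substr(res, s3, n)
  list(its2_start = e5 + 1L, its2_end = s3 - 1L,
       flank5 = flank5, flank3 = flank3,
       b9 = build_b9(flank5, flank3))
}

#' Build the B9 hybridization helix from the ITS2 flanks
#'
#' Finds the longest contiguous duplex formed by antiparallel hybridization
#' of the 3' end of the 5.8S rRNA with the 5' start of the 28S rRNA,
#' allowing Watson-Crick and wobble pairs. The highly conserved eight base
#' pair version of this stem is required for precise excision of the ITS2
#' during rRNA processing.
#'
#' @param flank5,flank3 Flank sequences (both at least the desired stem
#'   length; shorter inputs simply yield shorter stems).
#' @return A list of class `b9_helix`: `length` (bp) and `stem_pairs`
#'   (tibble: `offset5` 1-based from the 3' end of `flank5`, `offset3`
#'   1-based from the 5' start of `flank3`, `pair`, `type` WC/wobble).
#'   A stem shorter than 2 bp yields length 0 with a warning.
#' @export
build_b9 <- function(flank5, flank3) {
  r <- rev(strsplit(toupper(seq_residues(flank5)), "")[[1]])
  f <- strsplit(toupper(seq_residues(flank3)), "")[[1]]
  n5 <- length(r); n3 <- length(f)
  best <- list(len = 0L, o = NA_integer_, v0 = NA_integer_)
  for (o in seq(-(n3 - 1L), n5 - 1L)) {
    vs <- seq(max(1L, 1L - o), min(n3, n5 - o))
    if (length(vs) == 0L) next
    ok <- vapply(vs, function(v) {
      a <- r[v + o]; b <- f[v]
      a %in% c("A", "C", "G", "U") && b %in% c("A", "C", "G", "U") &&
        is_valid_pair(a, b)
    }, logical(1))
    # longest TRUE run
    rl <- rle(ok)
    if (!any(rl$values)) next
    lens <- rl$lengths[rl$values]
    maxlen <- max(lens)
    if (maxlen > best$len ||
        (maxlen == best$len && !is.na(best$o) && abs(o) < abs(best$o))) {
      idx <- which(rl$values & rl$lengths == maxlen)[1]
      v0 <- vs[sum(rl$lengths[seq_len(idx - 1L)]) + 1L]
      best <- list(len = maxlen, o = o, v0 = v0)
    }
  }
  if (best$len < 2L) {
    warning("no B9 duplex of at least 2 bp found", call. = FALSE)
    return(structure(list(length = 0L,
                          stem_pairs = tibble::tibble(offset5 = integer(),
                                                      offset3 = integer(),
                                                      pair = character(),
                                                      type = character())),
                     class = "b9_helix"))
  }
  v <- seq(best$v0, best$v0 + best$len - 1L)
  u <- v + best$o
  pair <- paste0(r[u], f[v])
  structure(list(
    length = best$len,
    stem_pairs = tibble::tibble(
      offset5 = u, offset3 = v, pair = pair,
      type = ifelse(pair %in% c("GU", "UG"), "wobble", "WC"))
  ), class = "b9_helix")
}

#' Excise the ITS2 from each amplicon of a sequence table
#'
#' Tibble-level wrapper over [locate_flanks()] and [build_b9()]. With
#' `assume_its2 = TRUE` the input is treated as pre-excised ITS2 and passed
#' through unchanged (boundaries `NA`); use this when boundary location
#' fails because the amplicons carry no flanks.
#'
#' @param records Tibble with columns `id`, `seq`.
#' @param model A [flank_model()].
#' @param assume_its2 Treat input as already-excised ITS2.
#' @return A tibble with columns `id`, `seq` (the ITS2), `its2_start`,
#'   `its2_end` (coordinates in the amplicon), `b9_len`.
#' @export
extract_its2 <- function(records, model = flank_model(), assume_its2 = FALSE) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (assume_its2) {
    return(dplyr::mutate(records, its2_start = NA_integer_,
                         its2_end = NA_integer_, b9_len = NA_integer_))
  }
  out <- purrr::map(seq_len(nrow(records)), function(k) {
    loc <- tryCatch(locate_flanks(records$seq[k], model), error = function(e) {
      stop("record '", records$id[k], "': ", conditionMessage(e),
           call. = FALSE)
    })
    tibble::tibble(
      id = records$id[k],
      seq = substr(records$seq[k], loc$its2_start, loc$its2_end),
      its2_start = loc$its2_start, its2_end = loc$its2_end,
      b9_len = loc$b9$length
    )
  })
  extra <- dplyr::select(records, -dplyr::any_of(c("seq")))
  dplyr::left_join(dplyr::bind_rows(out), extra, by = "id")
}
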
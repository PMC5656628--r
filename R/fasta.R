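#' Read RNA (or DNA) sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of RNA sequences. DNA input is accepted:
#' `T` is normalized to `U` on ingest. IUPAC ambiguity codes are legal;
#' any other character is an error naming the record and offset. Duplicate
#' ids are deduplicated by suffixing (`_2`, `_3`, ...) with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` (RNA residues) and `source`
#'   (the file path).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT"), tf)
#' read_its2_fasta(tf)
#' @export
read_its2_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  for (k in seq_along(seqs)) {
    if (nchar(seqs[k]) == 0L) {
      stop("empty sequence for record '", ids[k], "'", call. = FALSE)
    }
    chars <- strsplit(seqs[k], "")[[1]]
    bad <- which(!chars %in% IUPAC_CHARS)
    if (length(bad) > 0L) {
      stop("non-IUPAC character '", chars[bad[1]], "' in record '", ids[k],
           "' at offset ", bad[1], call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate FASTA ids deduplicated by suffix: ",
            paste(dup, collapse = ", "), call. = FALSE)
    ids <- dedup_ids(ids)
  }
  tibble::tibble(id = ids, seq = unname(seqs), source = path)
}

dedup_ids <- function(ids) {
  counts <- list()
  vapply(ids, function(id) {
    n <- (counts[[id]] %||% 0L) + 1L
    counts[[id]] <<- n
    if (n == 1L) id else paste0(id, "_", n)
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write sequences to a FASTA file
#'
#' @param records A tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_its2_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write structured alignments
#'
#' A structured alignment is stored as a plain-text exchange format: one
#' FASTA-like block per row holding the gapped residues on the first line
#' and the gapped dot-bracket string on the second, so sequence and
#' structure stay column-synchronized. The format round-trips losslessly.
#'
#' @param aln A `structured_alignment` (see [progressive_msa()]).
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   `structured_alignment`.
#' @export
write_structured_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "structured_alignment"))
  rows <- aln$rows
  if (nrow(rows) == 0L) stop("empty alignment", call. = FALSE)
  bad <- nchar(rows$aseq) != nchar(rows$adb)
  if (any(bad)) {
    stop("residue/structure length mismatch in row '", rows$id[which(bad)[1]],
         "'", call. = FALSE)
  }
  lines <- unlist(purrr::pmap(rows[c("id", "aseq", "adb")], function(id, aseq, adb) {
    c(paste0(">", id), aseq, adb)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_structured_alignment
#' @export
read_structured_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || length(lines) %% 3L != 0L) {
    stop("malformed structured alignment file: ", path, call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 3L)
  rows <- tibble::tibble(
    id = sub("^>", "", lines[idx]),
    aseq = lines[idx + 1L],
    adb = lines[idx + 2L]
  )
  new_structured_alignment(rows)
}
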
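#!/usr/bin/env Rscript

# One-time, network-requiring helper: downloads the Chloropicophyceae
# strain sequences listed in inst/extdata/accessions/strain_accessions.tsv
# from GenBank (NCBI E-utilities) and writes the fixtures the accession
# tests expect:
#   inst/extdata/accessions/its2_strains.fasta + its2_clades.tsv
#   inst/extdata/accessions/ssu_16s_concat.fasta + ssu_clades.tsv
#
# Run from the repository root:  Rscript scripts/fetch_accessions.R

acc_dir <- file.path("inst", "extdata", "accessions")
tab <- utils::read.delim(file.path(acc_dir, "strain_accessions.tsv"),
                         comment.char = "#", stringsAsFactors = FALSE)

efetch <- function(accs) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nucleotide&rettype=fasta&retmode=text&id=",
    paste(accs, collapse = ","))
  lines <- readLines(url)
  # split multi-FASTA into one sequence string per record, keyed by the
  # accession prefix of each header
  starts <- grep("^>", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(k) {
    paste(lines[(starts[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>(\\S+).*", "\\1", lines[starts])
  # efetch returns versioned accessions; index by the unversioned id
  names(seqs) <- sub("\\.\\d+$", "", names(seqs))
  seqs
}

write_fasta <- function(ids, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ids)) {
    writeLines(c(paste0(">", ids[k]), seqs[k]), con)
  }
}

message("fetching ITS sequences...")
its <- tab[nzchar(tab$acc_its) & tab$clade != "C", ]
its_seqs <- efetch(unique(its$acc_its))
write_fasta(its$id, unname(its_seqs[its$acc_its]),
            file.path(acc_dir, "its2_strains.fasta"))
utils::write.table(its[, c("id", "clade")],
                   file.path(acc_dir, "its2_clades.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("fetching and concatenating 18S + 16S sequences...")
ssu <- tab[nzchar(tab$acc_18s) & nzchar(tab$acc_16s) & tab$clade != "C", ]
s18 <- efetch(unique(ssu$acc_18s))
s16 <- efetch(unique(ssu$acc_16s))
# align each gene across strains before concatenation so the p-distance
# module sees homologous columns; mafft must be on PATH
align_with_mafft <- function(seqs, ids) {
  inf <- tempfile(fileext = ".fasta")
  outf <- tempfile(fileext = ".fasta")
  write_fasta(ids, seqs, inf)
  system2("mafft", c("--auto", "--quiet", inf), stdout = outf)
  set <- Biostrings::readBStringSet(outf)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}
a18 <- align_with_mafft(unname(s18[ssu$acc_18s]), ssu$id)
a16 <- align_with_mafft(unname(s16[ssu$acc_16s]), ssu$id)
concat <- paste0(a18[ssu$id], a16[ssu$id])
write_fasta(ssu$id, concat, file.path(acc_dir, "ssu_16s_concat.fasta"))
utils::write.table(ssu[, c("id", "clade")],
                   file.path(acc_dir, "ssu_clades.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("done; fixtures written under ", acc_dir)
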
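#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_its2_pipeline()]; everything is
#' validated up front so a misconfigured run fails before any folding
#' starts.
#'
#' @param flank_model A [flank_model()].
#' @param fold A [fold_params()].
#' @param hallmarks A [hallmark_config()].
#' @param scoring An [align_scoring()].
#' @param min_frac,conserved_frac Consensus-pair thresholds (see
#'   [consensus_pairs()]).
#' @param assume_its2 Treat input as pre-excised ITS2.
#' @param groups Optional named character vector mapping every sequence id
#'   to a clade label (enables clade-consensus CBC cells and group
#'   distances).
#' @param lineages Optional named character vector mapping ids to exactly
#'   two lineage labels (enables diagnostic-CBC reporting).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `its2_pipeline_config`.
#' @export
pipeline_config <- function(flank_model = its2cbc::flank_model(),
                            fold = fold_params(),
                            hallmarks = hallmark_config(),
                            scoring = align_scoring(),
                            min_frac = 0.9, conserved_frac = 0.7,
                            assume_its2 = FALSE,
                            groups = NULL, lineages = NULL, seed = 1L) {
  stopifnot(inherits(flank_model, "flank_model"),
            inherits(fold, "fold_params"),
            inherits(hallmarks, "hallmark_config"),
            inherits(scoring, "align_scoring"),
            min_frac > 0, min_frac <= 1, conserved_frac >= 0,
            conserved_frac <= 1)
  if (!is.null(lineages) && length(unique(lineages)) != 2L) {
    stop("lineages must map ids to exactly two labels", call. = FALSE)
  }
  structure(as.list(environment()), class = "its2_pipeline_config")
}

#' Run the full ITS2 CBC delimitation pipeline
#'
#' Orchestrates extract -> fold -> hallmark-annotate -> align -> CBC ->
#' distances -> delimitation as one reproducible run. Each stage writes a
#' plain file into `out_dir` so stages can be inspected or re-run
#' independently, and a manifest records the configuration hash, seed,
#' package version and per-file checksums; re-running with the same input
#' and config reproduces all outputs byte-identically.
#'
#' @param fasta Input FASTA of amplicons (or pre-excised ITS2 with
#'   `assume_its2`).
#' @param out_dir Run directory (created if needed).
#' @param config An [pipeline_config()].
#' @return Invisibly, a list with all stage objects: `records`,
#'   `structures`, `alignment`, `pairs`, `cbc`, `cbc_clades`, `dist`,
#'   `tree`, `calls`, `diagnostics`, `manifest`.
#' @export
run_its2_pipeline <- function(fasta, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "its2_pipeline_config"))
  if (!file.exists(fasta)) stop("input FASTA not found: ", fasta, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("read", read_its2_fasta(fasta))
  if (!is.null(config$groups)) {
    miss <- setdiff(records$id, names(config$groups))
    if (length(miss) > 0L) {
      stop("pipeline stage 'validate' failed: ids missing from groups: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(config$lineages)) {
    miss <- setdiff(records$id, names(config$lineages))
    if (length(miss) > 0L) {
      stop("pipeline stage 'validate' failed: ids missing from lineages: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  its2 <- stage("extract",
                extract_its2(records, config$flank_model,
                             assume_its2 = config$assume_its2))
  write_its2_fasta(its2, file.path(out_dir, "its2.fasta"))
  structures <- stage("fold", predict_structures(its2, config$fold,
                                                 config$hallmarks))
  writeLines(unlist(purrr::pmap(structures[c("id", "seq", "db")],
                                function(id, seq, db) c(paste0(">", id), seq, db))),
             file.path(out_dir, "structures.vienna"))
  aln <- stage("align", progressive_msa(structures, config$scoring))
  write_structured_alignment(aln, file.path(out_dir, "alignment.sa"))
  pairs <- stage("consensus",
                 consensus_pairs(aln, min_frac = config$min_frac,
                                 conserved_frac = config$conserved_frac,
                                 config = config$hallmarks,
                                 grouping = config$lineages %||% config$groups))
  utils::write.table(as.data.frame(pairs),
                     file.path(out_dir, "consensus_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cbc <- stage("cbc", cbc_matrix(aln, pairs))
  utils::write.table(cbc$cbc, file.path(out_dir, "cbc_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(as.data.frame(tidy_cbc_positions(cbc)),
                     file.path(out_dir, "cbc_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cbc_clades <- NULL
  if (!is.null(config$groups)) {
    cbc_clades <- stage("cbc_clades", cbc_matrix(aln, pairs, config$groups))
    utils::write.table(cbc_clades$cbc,
                       file.path(out_dir, "cbc_matrix_clades.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  dm <- stage("dist", p_distance_matrix(aln))
  utils::write.table(dm$d, file.path(out_dir, "dist.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  tree <- NULL
  if (length(dm$taxa) >= 3L) {
    tree <- stage("nj", nj_tree(dm))
    ape::write.tree(tree, file.path(out_dir, "nj.nwk"))
  }
  diagnostics <- NULL
  if (!is.null(config$lineages)) {
    labs <- unique(config$lineages)
    diagnostics <- stage("diagnostics", lineage_diagnostic_cbcs(
      aln, pairs,
      names(config$lineages)[config$lineages == labs[1]],
      names(config$lineages)[config$lineages == labs[2]]))
    utils::write.table(as.data.frame(diagnostics),
                       file.path(out_dir, "diagnostic_cbcs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  calls <- stage("delimit", delimit_species(cbc, dm))
  write_delimitation_report(calls, file.path(out_dir, "report.md"),
                            file.path(out_dir, "report.tsv"))
  manifest <- build_manifest(fasta, out_dir, config)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(records = records, its2 = its2, structures = structures,
                 alignment = aln, pairs = pairs, cbc = cbc,
                 cbc_clades = cbc_clades, dist = dm, tree = tree,
                 diagnostics = diagnostics, calls = calls,
                 manifest = manifest))
}

tidy_cbc_positions <- function(cbc) {
  taxa <- cbc$taxa
  combos <- utils::combn(taxa, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    t1 <- combos[1, k]; t2 <- combos[2, k]
    tibble::tibble(
      taxon1 = t1, taxon2 = t2,
      n_cbc = cbc$cbc[t1, t2], n_hcbc = cbc$hcbc[t1, t2],
      cbc_ids = paste(cbc$cbc_ids[[t1, t2]], collapse = ","),
      hcbc_ids = paste(cbc$hcbc_ids[[t1, t2]], collapse = ","))
  })
}

build_manifest <- function(fasta, out_dir, config) {
  cfg_str <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  outputs <- sort(setdiff(list.files(out_dir), "manifest.yaml"))
  sums <- tools::md5sum(file.path(out_dir, outputs))
  list(
    package = "its2cbc",
    version = as.character(utils::packageVersion("its2cbc")),
    seed = config$seed,
    input = unname(tools::md5sum(fasta)),
    config_hash = config_hash(cfg_str),
    outputs = stats::setNames(as.list(unname(sums)), outputs)
  )
}

config_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", h)
}
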
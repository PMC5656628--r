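# ---------------------------------------------------------------------------
# Synthetic ITS2 generator: clade-structured strain sets built from a
# four-helix consensus template with planted compensatory changes, so every
# pipeline stage can be tested against a known truth ledger.
#
# Loops and spacers are A-runs that mutate within {A, C}: neither base can
# pair with itself or the other, and the stem design below leaves them no
# profitable partner, so single-stranded regions stay single-stranded and
# the planted helix geometry is the unique fold optimum.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: two
#' lineages of three clades with four strains each; three lineage-level
#' CBCs planted in helices II and III distinguishing lineage 2 from
#' lineage 1; an 8-bp B9 stem formed by the 5.8S/28S flanks; a
#' lineage-2-only insertion of 7-9 nt between helices III and B9;
#' hallmark variants (one clade whose helix III YRRY motif reads UAAU, one
#' clade with a CxU helix II mismatch, one solitary strain with UxC); and
#' length-variable apical regions (helix I/II tips and the IIIa loop).
#'
#' @param seed Integer master seed. Every random draw is keyed by
#'   `(seed, unit id)` so adding strains never perturbs existing ones.
#' @param n_lineages,clades_per_lineage,strains_per_clade Study dimensions.
#' @param helix_len Named integer vector of stem lengths (bp) for helices
#'   `I`, `II`, `III`, `IIIa`, `III_ap` (apical continuation of III), `IV`.
#' @param planted_cbcs,planted_hcbcs Lists of planted pair changes:
#'   `list(helix=, stem=, to=c(b5, b3), level="lineage"|"clade",
#'   lineage=, clade=)`.
#' @param mismatch_variants List of helix II mismatch variants:
#'   `list(level=, lineage=, clade=, strain=, b5=, b3=)` (NULL fields keep
#'   the template U).
#' @param loop_mut_rate Per-base substitution rate in loops/spacers
#'   (clade-level; strains additionally mutate at half this rate).
#' @param stem_neutral_rate Per-pair rate of neutral wobble toggles
#'   (hCBC-compatible single-side changes) at non-planted stem positions.
#' @param indel_rate,indel_max_len Per-region probability and maximum size
#'   of indels in the variable regions (helix I tip, helix II tip, IIIa
#'   loop).
#' @param lineage_insertion `list(lineage=, len=c(min, max))`: spacer
#'   insertion between helices III and B9 (placed in the III-IV spacer),
#'   applied to the designated lineage only; length drawn per clade.
#' @param b9_stem_len B9 stem length (bp, default 8).
#' @param flank_mut_rate Substitution rate in the flank regions outside the
#'   conserved boundary motifs.
#' @return A list of class `its2_sim_config`.
#' @export
its2_sim_config <- function(seed = 1L,
                            n_lineages = 2L,
                            clades_per_lineage = 3L,
                            strains_per_clade = 4L,
                            helix_len = c(I = 9L, II = 8L, III = 10L,
                                          IIIa = 4L, III_ap = 4L, IV = 7L),
                            planted_cbcs = list(
                              list(helix = "II", stem = 2L, to = c("A", "U"),
                                   level = "lineage", lineage = 2L),
                              list(helix = "III", stem = 2L, to = c("U", "A"),
                                   level = "lineage", lineage = 2L),
                              list(helix = "III", stem = 9L, to = c("A", "U"),
                                   level = "lineage", lineage = 2L),
                              # YRRY UGGU -> UAAU variant: the two G-C pairs
                              # of the motif become A-U in one clade
                              list(helix = "III", stem = 5L, to = c("A", "U"),
                                   level = "clade", lineage = 2L, clade = 3L),
                              list(helix = "III", stem = 6L, to = c("A", "U"),
                                   level = "clade", lineage = 2L, clade = 3L)
                            ),
                            planted_hcbcs = list(
                              list(helix = "I", stem = 4L, to = c("G", "U"),
                                   level = "clade", lineage = 1L, clade = 2L),
                              list(helix = "II", stem = 7L, to = c("G", "U"),
                                   level = "clade", lineage = 2L, clade = 2L)
                            ),
                            mismatch_variants = list(
                              list(level = "clade", lineage = 1L, clade = 3L,
                                   b5 = "C", b3 = NULL),   # C x U
                              list(level = "strain", lineage = 1L, clade = 2L,
                                   strain = 4L, b5 = NULL, b3 = "C") # U x C
                            ),
                            loop_mut_rate = 0.03,
                            stem_neutral_rate = 0.01,
                            indel_rate = 0.5,
                            indel_max_len = 2L,
                            lineage_insertion = list(lineage = 2L,
                                                     len = c(7L, 9L)),
                            b9_stem_len = 8L,
                            flank_mut_rate = 0.02) {
  cfg <- structure(as.list(environment()), class = "its2_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_lineages >= 1, cfg$clades_per_lineage >= 1,
            cfg$strains_per_clade >= 1,
            cfg$loop_mut_rate >= 0, cfg$loop_mut_rate <= 1,
            cfg$stem_neutral_rate >= 0, cfg$stem_neutral_rate <= 1,
            cfg$b9_stem_len >= 2)
  if (any(cfg$helix_len < 1L)) {
    stop("helix of length 0 requested", call. = FALSE)
  }
  plants <- c(cfg$planted_cbcs, cfg$planted_hcbcs)
  keys <- character(0)
  for (p in plants) {
    if (!p$helix %in% names(cfg$helix_len)) {
      stop("planted change references unknown helix '", p$helix, "'",
           call. = FALSE)
    }
    if (p$stem < 1L || p$stem > cfg$helix_len[[p$helix]]) {
      stop("planted change references stem position ", p$stem,
           " outside helix ", p$helix, call. = FALSE)
    }
    if (!is_valid_pair(p$to[1], p$to[2])) {
      stop("planted to_pair ", paste(p$to, collapse = "-"),
           " is not a valid pair", call. = FALSE)
    }
    key <- paste(p$helix, p$stem, p$level, p$lineage, p$clade %||% 0)
    bp_key <- paste(p$helix, p$stem, p$level, p$lineage, p$clade %||% 0)
    if (bp_key %in% keys) {
      stop("contradictory planted changes at helix ", p$helix, " stem ",
           p$stem, call. = FALSE)
    }
    keys <- c(keys, bp_key)
  }
  invisible(cfg)
}

# --- deterministic keyed RNG ------------------------------------------------

unit_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer((seed * 48271 + h) %% 2147483629)
}

with_unit_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(unit_seed(seed, key))
  force(expr)
}

# --- template construction --------------------------------------------------

revcomp_rna <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# deterministic non-repetitive G-C dominated stem patterns; each helix reads
# the master pattern from its own offset so arms do not slide
# Stems are G-C pairs with G always on the 5\' arm, so 5\' arms carry no C
# and 3\' arms no G: single-stranded C-runs then cannot rewire one helix
# into another without losing score. One interior A-U pair per helix (the
# "register anchor"; helix III uses the U-A pairs of its UGGU motif) pins
# the pairing register so the designed geometry is the compact optimum the
# deterministic traceback prefers.
STEM_ANCHOR <- c(I = 5L, II = 6L, IIIa = 2L, III_ap = 2L, IV = 4L)

stem_pattern <- function(helix, n) {
  out <- rep("GC", n)
  a <- STEM_ANCHOR[helix]
  if (!is.na(a) && a <= n) out[a] <- "AU"
  out
}

el_run <- function(name, chars) {
  list(kind = "run", name = name,
       chars = if (length(chars) == 1L && nchar(chars[1]) > 1L)
         strsplit(chars, "")[[1]] else chars)
}

el_pair <- function(b5, b3) list(kind = "pair", b5 = b5, b3 = b3)
el_mm <- function(b5, b3) list(kind = "mm", b5 = b5, b3 = b3)

el_helix <- function(name, elems, content) {
  list(kind = "helix", name = name, elems = elems, content = content)
}

make_helix_elems <- function(helix, n, mm_after = NULL, override = list()) {
  pats <- stem_pattern(helix, n)
  elems <- list()
  for (k in seq_len(n)) {
    p <- override[[as.character(k)]] %||% strsplit(pats[k], "")[[1]]
    elems[[length(elems) + 1L]] <- el_pair(p[1], p[2])
    if (!is.null(mm_after) && k == mm_after) {
      elems[[length(elems) + 1L]] <- el_mm("U", "U")
    }
  }
  elems
}

b9_tail <- function(k) {
  pat <- c("G", "G", "U", "G", "G", "C", "A", "U")
  pat[((seq_len(k) - 1L) %% 8L) + 1L]
}

#' Build the consensus ITS2 template of a simulation
#'
#' Constructs the four-helix consensus the generator mutates: helix II
#' carries a UxU mismatch between its 4th and 5th pairs, the 5' arm of
#' helix III carries UGGU at stem positions 4-7 (paired U-A/G-C/G-C/U-A),
#' helix III bears a lateral IIIa branch and an apical continuation,
#' spacers have the configured fixed lengths, and the flanks hybridize
#' into a B9 stem of the configured length.
#'
#' @param cfg An [its2_sim_config()].
#' @return A list of class `its2_template`: `seq`, `db`, `partner`,
#'   `parts`, `annotation`, `flank5`, `flank3`, `flank_model`,
#'   `helix_map` (per-helix tibbles of stem position coordinates).
#' @export
make_template <- function(cfg = its2_sim_config()) {
  hl <- cfg$helix_len
  if (hl[["II"]] < 5L) stop("helix II must have at least 5 pairs to carry the UxU mismatch", call. = FALSE)
  if (hl[["III"]] < 9L) stop("helix III must have at least 9 pairs to carry UGGU and planted sites", call. = FALSE)
  yrry_override <- list(`4` = c("U", "A"), `5` = c("G", "C"),
                        `6` = c("G", "C"), `7` = c("U", "A"))
  parts <- list(
    el_run("B9_I", "AAAAAA"),
    el_helix("I", make_helix_elems("I", hl[["I"]]),
             list(el_run("loop_I", "AAAAA"))),
    el_run("I_II", "AAA"),
    el_helix("II", make_helix_elems("II", hl[["II"]], mm_after = 4L),
             list(el_run("loop_II", "AAAA"))),
    el_run("II_III", "AAAA"),
    el_helix("III", make_helix_elems("III", hl[["III"]],
                                     override = yrry_override),
             list(el_run("III_in1", "A"),
                  el_helix("IIIa", make_helix_elems("IIIa", hl[["IIIa"]]),
                           list(el_run("loop_IIIa", "AAA"))),
                  el_run("III_in2", "AA"),
                  el_helix("III_ap", make_helix_elems("III_ap", hl[["III_ap"]]),
                           list(el_run("loop_IIIap", "AAA"))),
                  el_run("III_in3", "A"))),
    el_run("III_IV", "AAAAA"),
    el_helix("IV", make_helix_elems("IV", hl[["IV"]]),
             list(el_run("loop_IV", "AAAA"))),
    el_run("IV_B9", "AAAAAA")
  )
  asm <- assemble_parts(parts)
  k <- cfg$b9_stem_len
  tail5 <- paste(b9_tail(k), collapse = "")
  motif_5p <- paste0("GAACGCACAUUG", tail5)
  motif_3p <- paste0(revcomp_rna(tail5), "ACCUCACGGGAA")
  flank5 <- paste0("ACGCAUACGC", motif_5p)
  flank3 <- paste0(motif_3p, "CGUACGCAUC")
  fm <- flank_model(motif_5p = motif_5p, motif_3p = motif_3p)
  structure(list(seq = asm$seq, db = asm$db, partner = asm$partner,
                 parts = parts,
                 annotation = annotate_helices(asm$partner),
                 flank5 = flank5, flank3 = flank3, flank_model = fm,
                 helix_map = asm$helix_map, run_map = asm$run_map),
            class = "its2_template")
}

# walk the element tree, emitting residues and pair coordinates
assemble_parts <- function(parts) {
  chars <- character(0)
  opens <- list()    # per-helix stacks of open positions
  pairs_acc <- list()
  helix_map <- list()
  run_map <- list()
  emit <- function(x) chars <<- c(chars, x)
  walk <- function(el) {
    if (el$kind == "run") {
      start <- length(chars) + 1L
      emit(el$chars)
      run_map[[el$name]] <<- c(start, length(chars))
      return(invisible())
    }
    stopifnot(el$kind == "helix")
    stem_i <- integer(0)
    stem_j <- integer(0)
    mm_pos <- list()
    # 5' arm
    kpair <- 0L
    for (e in el$elems) {
      emit(e$b5)
      if (e$kind == "pair") {
        kpair <- kpair + 1L
        stem_i[kpair] <- length(chars)
      } else {
        mm_pos[[length(mm_pos) + 1L]] <- c(i = length(chars), j = NA)
      }
    }
    for (sub in el$content) walk(sub)
    # 3' arm (reverse order)
    kk <- kpair
    mmk <- length(mm_pos)
    for (e in rev(el$elems)) {
      emit(e$b3)
      if (e$kind == "pair") {
        stem_j[kk] <- length(chars)
        kk <- kk - 1L
      } else {
        mm_pos[[mmk]]["j"] <- length(chars)
        mmk <- mmk - 1L
      }
    }
    helix_map[[el$name]] <<- list(
      stems = tibble::tibble(stem = seq_len(kpair), i = stem_i, j = stem_j),
      mm = mm_pos)
    pairs_acc[[length(pairs_acc) + 1L]] <<- cbind(stem_i, stem_j)
    invisible()
  }
  for (el in parts) walk(el)
  n <- length(chars)
  pr <- do.call(rbind, pairs_acc)
  partner <- partner_from_pairs(n, pr[, 1], pr[, 2])
  validate_structure(partner)
  list(seq = paste(chars, collapse = ""), db = render_dotbracket(partner),
       partner = partner, helix_map = helix_map, run_map = run_map)
}

# --- ledger application -----------------------------------------------------

# find (and modify) elements by helix / run name within the parts tree
modify_parts <- function(parts, fn) {
  walk <- function(el) {
    el <- fn(el)
    if (el$kind == "helix") el$content <- lapply(el$content, walk)
    el
  }
  lapply(parts, walk)
}

apply_ledger <- function(parts, ledger) {
  if (nrow(ledger) == 0L) return(parts)
  # pair and mismatch substitutions first, then run replacements (indels and
  # insertions are stored as full-run replacements)
  ord <- order(match(ledger$type, c("cbc", "hcbc", "neutral_wobble",
                                    "mm_variant", "loop_sub", "indel",
                                    "insertion", "flank_sub")))
  for (r in seq_len(nrow(ledger))[ord]) {
    e <- ledger[r, ]
    if (e$type %in% c("cbc", "hcbc", "neutral_wobble")) {
      to <- strsplit(e$to, "")[[1]]
      parts <- modify_parts(parts, function(el) {
        if (el$kind == "helix" && el$name == e$target) {
          kpair <- 0L
          for (t in seq_along(el$elems)) {
            if (el$elems[[t]]$kind == "pair") {
              kpair <- kpair + 1L
              if (kpair == e$index) {
                el$elems[[t]]$b5 <- to[1]
                el$elems[[t]]$b3 <- to[2]
              }
            }
          }
        }
        el
      })
    } else if (e$type == "mm_variant") {
      to <- strsplit(e$to, "")[[1]]
      parts <- modify_parts(parts, function(el) {
        if (el$kind == "helix" && el$name == e$target) {
          for (t in seq_along(el$elems)) {
            if (el$elems[[t]]$kind == "mm") {
              el$elems[[t]]$b5 <- to[1]
              el$elems[[t]]$b3 <- to[2]
            }
          }
        }
        el
      })
    } else if (e$type == "loop_sub") {
      parts <- modify_parts(parts, function(el) {
        if (el$kind == "run" && el$name == e$target) {
          el$chars[e$index] <- e$to
        }
        el
      })
    } else if (e$type %in% c("indel", "insertion")) {
      parts <- modify_parts(parts, function(el) {
        if (el$kind == "run" && el$name == e$target) {
          el$chars <- strsplit(e$to, "")[[1]]
        }
        el
      })
    }
  }
  parts
}

# --- strain generation ------------------------------------------------------

ledger_row <- function(strain, type, target, index, from, to) {
  tibble::tibble(strain = strain, type = type, target = target,
                 index = as.integer(index), from = from, to = to)
}

pair_str <- function(b5, b3) paste0(b5, b3)

wobble_toggle <- function(b5, b3) {
  switch(pair_str(b5, b3),
         GC = c("G", "U"), CG = c("U", "G"),
         AU = c("G", "U"), UA = c("U", "G"),
         GU = c("G", "C"), UG = c("C", "G"),
         NULL)
}

current_pair <- function(parts, helix, stem) {
  out <- NULL
  walk <- function(el) {
    if (el$kind == "helix") {
      if (el$name == helix) {
        kpair <- 0L
        for (e in el$elems) {
          if (e$kind == "pair") {
            kpair <- kpair + 1L
            if (kpair == stem) out <<- c(e$b5, e$b3)
          }
        }
      }
      lapply(el$content, walk)
    }
    invisible()
  }
  lapply(parts, walk)
  out
}

run_string <- function(parts, name) {
  out <- NULL
  walk <- function(el) {
    if (el$kind == "run" && el$name == name) out <<- paste(el$chars, collapse = "")
    if (el$kind == "helix") lapply(el$content, walk)
    invisible()
  }
  lapply(parts, walk)
  out
}

all_run_names <- function(parts) {
  out <- character(0)
  walk <- function(el) {
    if (el$kind == "run") out <<- c(out, el$name)
    if (el$kind == "helix") lapply(el$content, walk)
    invisible()
  }
  lapply(parts, walk)
  out
}

all_helix_names <- function(parts) {
  out <- character(0)
  walk <- function(el) {
    if (el$kind == "helix") {
      out <<- c(out, el$name)
      lapply(el$content, walk)
    }
    invisible()
  }
  lapply(parts, walk)
  out
}

#' Simulate a clade-structured ITS2 amplicon set with known truth
#'
#' Applies the configured planted changes (lineage- and clade-level CBCs
#' and hCBCs, helix II mismatch variants), neutral wobble toggles at
#' non-planted stem positions, loop substitutions (clade-level plus
#' strain-level at half rate, within the non-pairing loop alphabet),
#' indels in the declared variable regions, the lineage-restricted spacer
#' insertion, and flank substitutions outside the boundary motifs. Every
#' applied change is recorded in a ledger whose replay reproduces each
#' strain exactly. Deterministic: the same config and seed give
#' byte-identical output.
#'
#' @param cfg An [its2_sim_config()].
#' @return A list of class `its2_sim`: `amplicons` (tibble `id`, `seq`,
#'   `lineage`, `clade`, `strain`), `its2` (tibble with the true excised
#'   ITS2 and structure per strain), `truth` (class `its2_truth`:
#'   `template`, `ledger`, `strains`, `flank_model`, `config`).
#' @export
simulate_its2 <- function(cfg = its2_sim_config()) {
  tmpl <- make_template(cfg)
  plants <- c(lapply(cfg$planted_cbcs, function(p) c(p, list(kind = "cbc"))),
              lapply(cfg$planted_hcbcs, function(p) c(p, list(kind = "hcbc"))))
  for (p in plants) {
    from <- current_pair(tmpl$parts, p$helix, p$stem)
    ndiff <- sum(from != p$to)
    want <- if (p$kind == "cbc") 2L else 1L
    if (ndiff != want) {
      stop("planted ", p$kind, " at helix ", p$helix, " stem ", p$stem,
           " changes ", ndiff, " side(s) of ", pair_str(from[1], from[2]),
           "; a ", p$kind, " must change ", want, call. = FALSE)
    }
  }
  planted_keys <- vapply(plants, function(p) paste(p$helix, p$stem),
                         character(1))
  var_regions <- c("loop_I", "loop_II", "loop_IIIa")
  helix_names <- all_helix_names(tmpl$parts)
  seed <- cfg$seed

  strains <- list()
  ledgers <- list()
  for (L in seq_len(cfg$n_lineages)) {
    for (C in seq_len(cfg$clades_per_lineage)) {
      clade_key <- sprintf("L%dC%d", L, C)
      # clade-level loop substitutions
      clade_loop <- with_unit_seed(seed, paste0(clade_key, ".loop"), {
        draw_loop_subs(tmpl$parts, cfg$loop_mut_rate)
      })
      # lineage insertion (per clade length/content)
      ins_entry <- NULL
      if (!is.null(cfg$lineage_insertion) &&
          L == cfg$lineage_insertion$lineage) {
        ins_entry <- with_unit_seed(seed, paste0(clade_key, ".ins"), {
          lens <- seq(cfg$lineage_insertion$len[1],
                      cfg$lineage_insertion$len[2])
          len <- if (length(lens) == 1L) lens else sample(lens, 1L)
          ins <- strrep("A", len)
          old <- run_string(tmpl$parts, "III_IV")
          new <- paste0(substr(old, 1, 2), ins,
                        substr(old, 3, nchar(old)))
          ledger_row(NA_character_, "insertion", "III_IV", 3L, old, new)
        })
      }
      for (S in seq_len(cfg$strains_per_clade)) {
        id <- sprintf("L%dC%dS%d", L, C, S)
        led <- ledger_row(character(0), character(0), character(0),
                          integer(0), character(0), character(0))
        # planted pair changes
        for (p in plants) {
          hit <- (p$level == "lineage" && p$lineage == L) ||
            (p$level == "clade" && p$lineage == L && (p$clade %||% -1L) == C)
          if (!hit) next
          from <- current_pair(tmpl$parts, p$helix, p$stem)
          led <- dplyr::bind_rows(led, ledger_row(
            id, p$kind, p$helix, p$stem, pair_str(from[1], from[2]),
            pair_str(p$to[1], p$to[2])))
        }
        # mismatch variants
        for (v in cfg$mismatch_variants) {
          hit <- switch(v$level,
                        lineage = v$lineage == L,
                        clade = v$lineage == L && v$clade == C,
                        strain = v$lineage == L && v$clade == C &&
                          v$strain == S)
          if (!isTRUE(hit)) next
          led <- dplyr::bind_rows(led, ledger_row(
            id, "mm_variant", "II", 1L, "UU",
            pair_str(v$b5 %||% "U", v$b3 %||% "U")))
        }
        # neutral wobble toggles at non-planted stem positions
        led <- dplyr::bind_rows(led, with_unit_seed(seed, paste0(id, ".stem"), {
          out <- list()
          for (h in helix_names) {
            nst <- nrow(tmpl$helix_map[[h]]$stems)
            for (st in seq_len(nst)) {
              if (paste(h, st) %in% planted_keys) next
              if (stats::runif(1) < cfg$stem_neutral_rate) {
                from <- current_pair(tmpl$parts, h, st)
                to <- wobble_toggle(from[1], from[2])
                if (!is.null(to)) {
                  out[[length(out) + 1L]] <- ledger_row(
                    id, "neutral_wobble", h, st,
                    pair_str(from[1], from[2]), pair_str(to[1], to[2]))
                }
              }
            }
          }
          dplyr::bind_rows(out)
        }))
        # clade-level + strain-level loop substitutions
        led <- dplyr::bind_rows(led, dplyr::mutate(clade_loop, strain = id))
        led <- dplyr::bind_rows(led, with_unit_seed(seed, paste0(id, ".loop"), {
          dplyr::mutate(draw_loop_subs(tmpl$parts, cfg$loop_mut_rate / 2),
                        strain = id)
        }))
        # indels in variable regions (applied to the post-substitution runs,
        # so run replacements are computed after subs below)
        if (!is.null(ins_entry)) {
          led <- dplyr::bind_rows(led, dplyr::mutate(ins_entry, strain = id))
        }
        led_indel <- with_unit_seed(seed, paste0(id, ".indel"), {
          out <- list()
          for (rg in var_regions) {
            if (stats::runif(1) >= cfg$indel_rate) next
            delta <- sample(c(-seq_len(cfg$indel_max_len),
                              seq_len(cfg$indel_max_len)), 1L)
            old <- run_string(apply_ledger(tmpl$parts, led), rg)
            if (delta < 0) {
              keep <- max(3L, nchar(old) + delta)
              new <- substr(old, 1, keep)
            } else {
              new <- paste0(old, strrep("A", delta))
            }
            if (new != old) {
              out[[length(out) + 1L]] <- ledger_row(id, "indel", rg, 1L,
                                                    old, new)
            }
          }
          dplyr::bind_rows(out)
        })
        led <- dplyr::bind_rows(led, led_indel)
        # flank substitutions (prefix/suffix outside the boundary motifs)
        fl <- with_unit_seed(seed, paste0(id, ".flank"), {
          mutate_flanks(tmpl$flank5, tmpl$flank3, tmpl$flank_model,
                        cfg$flank_mut_rate, id)
        })
        led <- dplyr::bind_rows(led, fl$ledger)
        # realize the strain
        parts <- apply_ledger(tmpl$parts, led)
        asm <- assemble_parts(parts)
        strains[[id]] <- tibble::tibble(
          id = id, lineage = L, clade = C, strain = S,
          seq = asm$seq, db = asm$db,
          flank5 = fl$flank5, flank3 = fl$flank3,
          amplicon = paste0(fl$flank5, asm$seq, fl$flank3),
          its2_start = nchar(fl$flank5) + 1L,
          its2_end = nchar(fl$flank5) + nchar(asm$seq))
        ledgers[[id]] <- led
      }
    }
  }
  strains <- dplyr::bind_rows(strains)
  ledger <- dplyr::bind_rows(ledgers)
  truth <- structure(list(template = tmpl, ledger = ledger,
                          strains = strains,
                          flank_model = tmpl$flank_model, config = cfg),
                     class = "its2_truth")
  amplicons <- dplyr::select(strains, "id", seq = "amplicon", "lineage",
                             "clade", "strain")
  its2 <- dplyr::select(strains, "id", "seq", "db", "lineage", "clade",
                        "strain")
  structure(list(amplicons = amplicons, its2 = its2, truth = truth),
            class = "its2_sim")
}

draw_loop_subs <- function(parts, rate) {
  out <- list()
  for (rn in all_run_names(parts)) {
    s <- strsplit(run_string(parts, rn), "")[[1]]
    for (k in seq_along(s)) {
      if (stats::runif(1) < rate) {
        to <- if (s[k] == "A") "C" else "A"
        out[[length(out) + 1L]] <- ledger_row(NA_character_, "loop_sub", rn,
                                              k, s[k], to)
      }
    }
  }
  if (length(out) == 0L) {
    ledger_row(character(0), character(0), character(0), integer(0),
               character(0), character(0))
  } else {
    dplyr::bind_rows(out)
  }
}

mutate_flanks <- function(flank5, flank3, fm, rate, id) {
  led <- list()
  f5 <- strsplit(flank5, "")[[1]]
  f3 <- strsplit(flank3, "")[[1]]
  # mutable regions: the prefix of flank5 (before the motif) and the suffix
  # of flank3 (after the motif); the boundary motifs and B9 stem stay intact
  pre5 <- seq_len(nchar(flank5) - nchar(fm$motif_5p))
  suf3 <- seq(nchar(fm$motif_3p) + 1L, length(f3))
  for (k in pre5) {
    if (stats::runif(1) < rate) {
      to <- sample(setdiff(c("A", "C", "G", "U"), f5[k]), 1L)
      led[[length(led) + 1L]] <- ledger_row(id, "flank_sub", "flank5", k,
                                            f5[k], to)
      f5[k] <- to
    }
  }
  for (k in suf3) {
    if (stats::runif(1) < rate) {
      to <- sample(setdiff(c("A", "C", "G", "U"), f3[k]), 1L)
      led[[length(led) + 1L]] <- ledger_row(id, "flank_sub", "flank3", k,
                                            f3[k], to)
      f3[k] <- to
    }
  }
  list(flank5 = paste(f5, collapse = ""), flank3 = paste(f3, collapse = ""),
       ledger = if (length(led) > 0L) dplyr::bind_rows(led) else
         ledger_row(character(0), character(0), character(0), integer(0),
                    character(0), character(0)))
}

#' Replay a strain's ledger against the template
#'
#' Rebuilds a strain's ITS2 sequence and structure (and flanks) from the
#' template plus the recorded ledger entries; the result must equal the
#' stored strain exactly. This is the generator's core invariant.
#'
#' @param truth An `its2_truth`.
#' @param id Strain id.
#' @return A list: `seq`, `db`, `flank5`, `flank3`, `amplicon`.
#' @export
replay_strain <- function(truth, id) {
  stopifnot(inherits(truth, "its2_truth"), id %in% truth$strains$id)
  led <- dplyr::filter(truth$ledger, .data$strain == id)
  parts <- apply_ledger(truth$template$parts,
                        dplyr::filter(led, .data$type != "flank_sub"))
  asm <- assemble_parts(parts)
  f5 <- strsplit(truth$template$flank5, "")[[1]]
  f3 <- strsplit(truth$template$flank3, "")[[1]]
  fl <- dplyr::filter(led, .data$type == "flank_sub")
  for (r in seq_len(nrow(fl))) {
    if (fl$target[r] == "flank5") f5[fl$index[r]] <- fl$to[r]
    else f3[fl$index[r]] <- fl$to[r]
  }
  f5 <- paste(f5, collapse = "")
  f3 <- paste(f3, collapse = "")
  list(seq = asm$seq, db = asm$db, flank5 = f5, flank3 = f3,
       amplicon = paste0(f5, asm$seq, f3))
}

#' True planted diagnostic positions of a simulation
#'
#' Returns, for one strain, the sequence coordinates (i, j) of the pairs
#' at which lineage-level CBCs were planted - the positions an end-to-end
#' run must recover as diagnostic between the lineages.
#'
#' @param truth An `its2_truth`.
#' @param id Strain id (coordinates are in this strain's ITS2; indels only
#'   occur in loops, so stem coordinates shift together).
#' @return A tibble: `helix`, `stem`, `i`, `j` (coordinates in the strain's
#'   own ITS2 sequence).
#' @export
truth_diagnostic_positions <- function(truth, id) {
  stopifnot(inherits(truth, "its2_truth"))
  cfg <- truth$config
  lin_cbcs <- purrr::keep(cfg$planted_cbcs, ~ .x$level == "lineage")
  led <- dplyr::filter(truth$ledger, .data$strain == id,
                       .data$type != "flank_sub")
  parts <- apply_ledger(truth$template$parts, led)
  asm <- assemble_parts(parts)
  purrr::map_dfr(lin_cbcs, function(p) {
    st <- asm$helix_map[[p$helix]]$stems
    tibble::tibble(helix = p$helix, stem = p$stem,
                   i = st$i[st$stem == p$stem], j = st$j[st$stem == p$stem])
  })
}
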
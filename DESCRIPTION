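Package: its2cbc
Title: ITS2 Secondary-Structure Species Delimitation by Compensatory Base Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for delimiting species of picoplanktonic
    green algae (and other eukaryotes) from the secondary structure of the
    second internal transcribed spacer (ITS2) of the nuclear rRNA operon.
    Locates ITS2 boundaries inside 5.8S-ITS2-28S amplicons via conserved
    flanking motifs and validates the B9 hybridization stem, predicts nested
    secondary structures by weighted base-pair maximization with near-optimal
    candidate enumeration, selects candidates by the universal ITS2 hallmarks
    (four-helix topology, helix II pyrimidine-pyrimidine mismatch, helix III
    YRRY motif), aligns sequences jointly with their structures through a
    12-state progressive aligner, classifies base-pair changes between taxa
    into compensatory (CBC), hemi-compensatory (hCBC) and pairing-breaking
    categories, computes complete-deletion p-distances, and combines the
    evidence into per-pair species-boundary calls. Ships a synthetic-data
    generator that plants known compensatory changes so the whole pipeline is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
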
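---
title: "Delimiting species from ITS2 secondary structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting species from ITS2 secondary structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2cbc)
```

## The scientific problem

Morphologically indistinct microalgae — picoplanktonic green algae are the
motivating case — are routinely delimited into species with molecular
evidence. One widely used line of evidence comes from the second internal
transcribed spacer (ITS2) of the nuclear rRNA operon. The ITS2 sequence
diverges quickly, but its transcript folds into a secondary structure with
conserved features ("hallmarks") that are required for rRNA processing:
four helices (I–IV), a pyrimidine × pyrimidine mismatch in helix II, a
YRRY motif on the 5′ side of helix III, tightly constrained spacers
between helices I–II and II–III, and, flanking the ITS2 itself, the B9
stem formed by hybridization of the 3′ end of the 5.8S rRNA with the 5′
start of the 28S rRNA.

Because the structure is conserved while the sequence drifts, paired
positions can be compared *as pairs* between organisms. A **compensatory
base change (CBC)** replaces both bases of a pair while retaining pairing
(e.g. G–C → A–U); a **hemi-CBC (hCBC)** replaces one base while retaining
pairing (e.g. G–C → G–U); a change that destroys pairing is a non-CBC.
The presence of at least one CBC between two organisms is a strong
indicator that they are distinct species, whereas the *absence* of CBCs is
not evidence of conspecificity. `its2cbc` implements this analysis
end-to-end: ITS2 excision, structure prediction and hallmark-guided
selection, sequence+structure alignment, CBC classification, complete-
deletion p-distances, and per-pair species-boundary calls — together with
a synthetic-data generator that plants known CBCs so the whole chain is
testable against ground truth.

## Pipeline and model choices

### Boundary annotation and the B9 stem

ITS2 boundaries inside a 5.8S–ITS2–28S amplicon are located by scanning
for two conserved flank motifs (the 5.8S 3′ end and the 28S 5′ start)
within a window (default 60 nt) from each end, allowing up to
`max_mismatch` (default 3) IUPAC-aware mismatches. Production boundary
annotators use profile HMMs trained on curated alignments; the shipped
position-specific motifs are approximations that behave identically on
well-conserved flanks, and both motifs and thresholds are configuration
(`flank_model()`), not constants. Ties between equal-scoring hits are
resolved in favour of the hit pair that maximizes the resulting B9 stem
length — the structural motif required for precise ITS2 excision — then
the 5′-most hit. `build_b9()` finds the longest contiguous antiparallel
duplex (Watson–Crick + wobble) between the flanks; a stem shorter than
2 bp is reported as absent.

### Folding: weighted pair maximization, not thermodynamics

Structures are predicted by maximizing a weighted count of canonical
pairs (G-C = 3, A-U = 2, G-U = 1 by default; `fold_params()`) over all
pseudoknot-free structures with hairpin loops of at least `min_loop = 3`
nt — the classic interval dynamic program — rather than by a
nearest-neighbour free-energy model. This is deliberate: the published
ITS2 workflow did not pick structures by free energy either, but by the
presence of the hallmarks among alternative foldings, and a
pair-maximization model is self-contained and exactly testable against an
exhaustive oracle (`brute_force_fold()`, guarded to 16 nt). Temperature is
therefore not modelled, and no attempt is made to reproduce any specific
thermodynamic folder's output.

Numerical determinism: the traceback always pairs the 5′-most base of the
open interval with the smallest admissible partner; near-optimal
structures are enumerated through the unambiguous first-position
decomposition and ranked by score, then lexicographic dot-bracket order.
Two caveats discovered and documented here rather than hidden:

* **Lonely pairs** (helices of length 1) are stripped from candidates as
  a deterministic post-filter (`forbid_lonely_pairs = TRUE`), not inside
  the DP grammar. The DP optimum therefore agrees exactly with the
  unconstrained oracle, while annotation never sees spurious one-pair
  "helices". The post-filter score can differ between co-optimal
  tracebacks, so score-level properties are stated for the unfiltered DP.
* **Reverse-complement invariance** of the fold score holds exactly for
  Watson–Crick-only weights; a G-U wobble maps to the non-pairing A-C
  under reverse complement, so the property cannot hold once wobbles are
  scored. A zero weight disables a pair type for such checks.

### Hallmark annotation, selection, and comparative transfer

`annotate_helices()` groups pairs into helices (stacked runs merged
across internal loops of at most `bulge_tol = 2` nt per side), labels the
four longest root-level helices I–IV in 5′→3′ order, and labels the
5′-most branch off helix III as IIIa. `check_hallmarks()` locates the
Y–Y mismatch (as a 1×1 internal loop of pyrimidines in helix II,
reporting the actual bases, e.g. U×U or C×U), scans the helix III 5′ arm
for a YRRY window (reporting e.g. UGGU or UAAU), compares the I–II and
II–III spacer lengths against configured expectations, records the first
two base pairs of helices I–III, and checks — but never scores — the AGG
motif at the base of helix IV, which is absent from these structures.
The aggregate score is `4·(four helices) + 2·(Y–Y) + 2·(YRRY) + 1·(each
spacer ok)`; the weights are configuration, chosen so topology dominates.
Expected spacer lengths and first-pair identities vary across lineages
and are stored as editable configuration, not asserted constants.

Pure pair-maximization folding of *individual* sequences is unreliable:
a single wobble pair or a stray loop mutation can make some rearranged
structure outscore the biological one. The published workflow solved
this by choosing structures using hallmarks *and* similarity to the other
structures in the dataset; template-based ITS2 annotation does the same
by homology modelling. `predict_structures()` follows that practice: it
folds every sequence, selects each sequence's hallmark-best candidate,
votes a consensus structure from all the individual folds (pairs
supported by at least half the strains, mapped through pairwise
alignments onto a scaffold), and transfers that consensus onto each
strain by homology (`structure_by_homology()`), adopting the transfer
wherever it scores at least as well on the hallmarks as the strain's own
fold. Only the pairing hypothesis is shared; every strain keeps its own
bases, so CBC analysis is untouched. `transfer = FALSE` restores fully
independent folds.

### Sequence+structure alignment

Sequences are aligned jointly with their structures over a 12-letter
alphabet (base × {unpaired, open, close}; ambiguity codes are forced
unpaired). Pairwise alignment is global affine-gap (match 2, base
mismatch −1, an additional −1 when pairing states differ, gaps −3/−1;
`align_scoring()`), with a deterministic tie-break (diagonal, then up).
The multiple alignment is progressive: a guide tree is built by neighbor
joining on p-distances from preliminary sequence-only pairwise
alignments (or supplied by the user), and profiles are merged along it.
Structures are fixed inputs — columns are never re-folded after
alignment. Manual curation of alignments, which the original analysis
used extensively, is replaced by this automatic procedure; a hand-edited
alignment can be imported through the structured-alignment text format,
so manual edits remain possible but are never required. Alignment-
dependent numbers can therefore only be reproduced with tolerance.

### CBC analysis

`consensus_pairs()` operationalizes "the conserved regions of helices I,
II and III": a column pair must be paired in at least `min_frac = 0.9`
of rows, lie in helix I, II or III (by per-row annotation majority;
helix IV and the unconserved apical/IIIa regions are excluded), be
consistently nested, and pass a base-conservation filter
(`conserved_frac = 0.7` per column). The conservation filter is applied
**within each lineage** when a grouping is supplied: consensus diagrams
apply majority rules per lineage, and a single global filter would
discard exactly the lineage-diagnostic columns the analysis is after —
a 50/50 split between two lineages can never reach 70% globally. This
operationalization is the package's largest judgment call; both
thresholds are configuration.

Counting is phenetic (pairwise), not ancestral-state-aware — conflicting
branching patterns among single-gene phylogenies make the phylogenetic
approach inapplicable here. Pairs of taxa are classified at every
consensus bp; gaps or ambiguity codes make a position not comparable and
excluded from counts. Clade-vs-clade cells are computed between clade
majority-consensus rows; a per-strain mode is the default. Consensus bp
ids are numbered 1..K in 5′→3′ order within each analysis and are not
expected to coincide with any previously published numbering.

### Distances and delimitation

p-distances use complete deletion: every column containing a gap or
ambiguity in any row is removed once, globally, before counting
mismatches — matching the convention the reference distance values
assume. Pairwise deletion is available behind a flag with a warning.
Between-group distances are reported both as the unweighted mean over all
cross pairs and as the maximum, because published statements of the form
"as high as x%" refer to the maximum while "the distance between
lineages" is most naturally the mean. `delimit_species()` calls a pair
*distinct* on ≥1 CBC, reserves *same* for identical ITS2 (zero distance,
no changes), and otherwise reports *not-separable-by-CBC* with hCBC
counts and distances as notes; no distance threshold is invented, since
the evidence for species status is argued from CBCs plus ecology, not a
distance cutoff.

## The synthetic generator

`its2_sim_config()` defaults encode the study conditions the pipeline is
tested against: 2 lineages × 3 clades × 4 strains; three lineage-level
CBCs planted in helices II and III that distinguish lineage 2 from
lineage 1; an 8-bp B9 stem; a lineage-2-only insertion of 7–9 nt between
helices III and B9; one clade whose YRRY motif reads UAAU; one clade with
a C×U helix II mismatch and one solitary strain with U×C; and
length-variable apical regions (helix I/II tips, IIIa loop). Unstated
magnitudes were fixed once at values realistic for conspecific ITS2
sets, which are nearly identical within clades: loop substitutions at
3% per base at clade level plus 1.5% at strain level, neutral wobble
toggles at 1% per stem pair (never at planted positions), indels of at
most 2 nt in the declared variable regions with probability 0.5, and
flank substitutions at 2% outside the boundary motifs. Every random draw
is keyed by `(seed, unit id)`, so adding strains never perturbs existing
ones, and each applied change is recorded in a ledger whose replay
(`replay_strain()`) reproduces every strain exactly.

Two deliberate idealizations matter for interpreting test results.
First, single-stranded regions are A-runs mutating within {A, C}, and
stems are G-C pairs with G on the 5′ arm plus one interior A-U "register
anchor" per helix (helix III's anchors are the U-A pairs of its UGGU
motif). Under pair-maximization scoring this makes the planted geometry
the compact optimum and prevents single-stranded regions from rewiring
helices. Real ITS2 loops are not compositionally segregated, real stems
are not G-C oriented one way, and real folding is thermodynamic — so a
green planted-recovery suite demonstrates that the pipeline's logic is
correct, not that the folder would recover real structures
single-handedly (that is exactly why the comparative transfer step
exists). Second, indels never occur inside stems, so structure transfer
across strains is length-robust by construction.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on generated data:
folding-oracle agreement on 500 random sequences of length ≤ 16;
the full 256-combination CBC truth table; the end-to-end planted-CBC
recovery on 20 seeded replicates of the default 24-strain design
(~135-nt ITS2 plus 30-nt flanks); NJ topology recovery on 25 random
additive trees of 6–10 taxa; and hand-computed p-distance toys. These
sizes keep a full run in minutes on one core while exercising every
module at its documented tolerance. Internally all coordinates are
1-based inclusive (the R convention), which is also the convention of
every user-facing report. Degenerate inputs are defined, not crashed on:
sequences shorter than `min_loop + 2` fold to all-unpaired with a
warning, flankless amplicons raise side-specific boundary errors with a
documented pre-excised fallback, empty consensus-pair sets warn, and a
B9 duplex under 2 bp reports length 0.

## Known limitations

* The folder is a scoring toy by design; on real data, structure quality
  rests on hallmark selection plus comparative transfer, and a
  thermodynamic folder can be slotted in by supplying dot-bracket
  structures directly (`parse_dotbracket()`, `read_structured_alignment()`).
* Published per-cell CBC counts depend on a manually curated alignment
  that cannot be replayed exactly; alignment-dependent quantities are
  matched with tolerance, and consensus bp numbering is internal.
* The boundary motifs are stand-ins for trained profile HMMs and should
  be re-estimated for taxa with divergent 5.8S/28S flanks.
* Delimitation integrates no evidence beyond CBCs and distances
  (pigments, genome size and morphology enter only as free-text notes).
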
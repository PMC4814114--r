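---
title: "Contact-based alignment of GPCR transmembrane bundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-based alignment of GPCR transmembrane bundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grossalign)
```

# The problem

G-protein coupled receptors share a seven-transmembrane-helix (TM) fold even
where pairwise sequence similarity falls to ~20%, far below what profile or
HMM aligners handle reliably; those aligners also introduce gaps inside TM
helices, which makes the resulting alignments useless as homology-modeling
templates.  `grossalign` aligns TM domains *structurally*: residues of two
receptors correspond when they occupy the same position in the shared helix
bundle, and that correspondence is found by maximizing the number of
inter-helical residue contacts the two structures have in common.  Because
each TM helix is treated as gapless, the alignment of a whole protein is
fully determined by seven anchor residues — the Ballesteros–Weinstein (BW)
n.50 reference of each helix — plus the seven TM ranges.

# The model, step by step

## Inter-helical contacts

Two residues on different helices are in contact when **any** pair of their
heavy atoms lies closer than the sum of the atoms' van der Waals radii plus a
slack of 0.6 Å (`contact_params()`).  The radii default to the Bondi values
(C 1.70, N 1.55, O 1.52, S 1.80 Å) and are overridable; the slack widens the
shell to capture packing interactions without being a hydrogen-bond
criterion — contacts here are deliberately chemically nonspecific, because
residue identity is not conserved across receptor classes even where the
packing is.  The rule is a strict inequality, so a pair at exactly the
threshold is *not* a contact; the sharpness of the cutoff is tested on
constructed geometries 0.01 Å on either side of it.

Contacts are canonicalized as unordered BW-position pairs with the
lower-numbered helix first (`"2.45-3.42"`).  Relabeling a contact set under a
different anchor choice is pure arithmetic on the stored residue numbers, a
property the anchor search exploits heavily.

## Anchor search

Given a target structure, an initial anchor guess, and a panel of
BW-labeled reference contact sets, `search_anchors()` scores every candidate
anchor placement by the *cumulative* number of contact occurrences shared
with the panel (a contact found in 20 reference structures contributes 20).
Shifts of up to ±`window` residues per helix are allowed (the classic choice
is 10) and shifts that push an anchor outside its TM range are skipped.

The joint space of per-helix shifts is huge (21^7 at window 10), but a shift
of helix *n* only relabels contacts involving helix *n*, so the default
strategy is coordinate ascent: scan one helix exhaustively with the other
six fixed, and iterate to convergence.  For additive landscapes this is
exact; because the score really is a sum of helix-pair terms, coupling can
in principle trap the ascent, so an exhaustive `mode = "joint"` is provided
for small windows (guarded at 2×10^5 candidates).  Both modes agree on the
planted two-helix perturbations in the test suite.  Ties are broken by lower
Cα RMSD against a chosen reference structure and then by smaller total
|shift|; the tie rule is explicit because the enumeration order should never
decide an alignment.  A `pin` argument fixes chosen helices to a given
anchor — the mechanism for keeping a receptor's alignment consistent with a
close homolog when the top two candidates are nearly tied — and pinned
anchors are visible in the output ranking.

## Superposition

`superpose_rmsd()` pairs residues with equal BW labels over the maximal
overlapping extent of all seven helices and computes the optimal least-squares
rigid-superposition Cα RMSD (Kabsch, via SVD with a proper-rotation sign
correction).  RMSD is reported alongside the contact score but is not the
selection criterion: helices with splayed extracellular ends dominate RMSD
and can prefer misregistered alignments, which is the reason the method
optimizes contacts instead.  The implementation is cross-checked in the test
suite against an independent closed-form quaternion (Horn) superposition.

## Conserved contacts and activation hot-spots

`conserved_contacts()` counts each contact over a panel of structures from
one class and keeps those above a threshold (for a 24-structure class-A
panel the classic threshold is 23, i.e. "all but one").
`chico_contacts()` then intersects that list with the contact sets of the
structures from the other classes; contacts surviving in *all* of them
define the superfamily structural fold (CHICOs).  Whether "all" means every
structure or every class is ambiguous when a class contributes two
structures; the default requires every structure, and `min_count` relaxes
it.

`compare_states()` opposes panels of inactive and active structures:
contacts present in all structures of one state and absent from every
structure of the other are the activation-rewired contacts, and the residues
participating in them are the NACHO roster (`nacho_report()` adds the
per-residue multiplicity — how many changed contacts a residue joins).  The
strict all-or-none criterion is the default because the published analyses
used accepted fully-active/inactive pairs only; `min_present`/`max_other`
expose the tolerant variant for noisy panels.

## TM-only similarity and phylogeny

`tm_similarity()` compares two aligned proteins column-by-column over the
seven helices — gapless by construction — and reports 100 × (columns with a
positive substitution-matrix entry) / (columns compared).  BLOSUM62 is the
default matrix (taken from Biostrings' canonical copy); any whitespace-table
matrix such as GPCRtm can be supplied, and the planted-offset tests require
the chosen matrix not to change the optimal offset.  Columns outside either
protein's TM extent are clipped, and `group_shift_scan()` repeats the
computation for ±5-residue displacements of one group's anchor on one helix:
the offset maximizing the mean cross-pair similarity is the alignment the
sequences themselves support, which is how weakly-alignable subfamilies
(bitter-taste, vomeronasal) are checked against the main classes.

`cluster_tree()` builds a UPGMA (average-linkage) tree on the dissimilarity
100 − similarity.  UPGMA is implemented in the package rather than delegated
so that the tie rule is pinned down — among minimum-dissimilarity pairs the
lexicographically smallest pair of cluster labels merges first — making tree
topology invariant under input permutation; `stats::hclust` serves as an
independent oracle in the tests on tie-free matrices.  A greedy
`"sequential"` mode (grow one cluster by absorbing the outsider with the
lowest average dissimilarity) is provided as an alternative reading of the
clustering description in the original analysis.  Branch lengths follow the
ultrametric convention (merge at height *d*/2), so leaf-to-leaf path lengths
reproduce cophenetic dissimilarities exactly; Newick I/O round-trips through
`ape`.

## Variants

`map_variants()` converts sequence positions to BW labels through the
alignment table (positions outside all TM ranges map to NA), and
`score_variants()` ranks them by

```
score = d_NACHO + d_CHICO − mult_NACHO − mult_CHICO + B62(wt, mut)
```

where distances are |ΔBW index| to the nearest roster residue **on the same
helix** (sequence positions, not Å — the rosters live on helices and BW
offsets are sequence offsets), multiplicities are the contact counts at that
nearest roster residue, and the substitution term is the raw matrix entry
with its sign.  Lower scores flag likelier structural damage.  When a helix
carries no roster residue the distance is set to a sentinel of 20 — beyond
any TM length, so such variants rank after genuinely roster-adjacent ones
while the score stays finite and totally ordered.  `summarize_variants()`
tabulates counts and disease-annotation percentages for the standard strata
(all, TM, non-TM, CHICO/CHICO-only, NACHO/NACHO-only, both), excluding
olfactory and unassigned receptors from the stratified rows by default, as
in the published summaries.

## Rigid helix moves

`decompose_move()` measures how far one helix must move between two
structures: after a global whole-bundle superposition (skippable for inputs
already in one frame), the helix's displacement is split into translation
along the first structure's helix axis (signed, positive extracellular),
perpendicular translation (magnitude), the tilt between the two axes, the
residual spin about the axis, and the RMSD left after a full per-helix
rigid refit.  The centroid split is Pythagorean by construction and is
asserted to 10⁻⁶ in the tests.

The helix axis deserves a note: the principal component of the raw Cα cloud
is biased by the unbalanced helical phase (up to ~2° for a 26-residue
helix), so `fit_axis()` instead reconstructs per-residue helix-center points
from second differences of consecutive Cα positions — which point radially
inward on an ideal helix — and fits the line through those centers.  This is
exact for ideal helical geometry of any length and stays within 2° of truth
at 0.2 Å coordinate noise.  Axis orientation follows membrane topology:
odd-numbered TMs run extracellular→intracellular along the sequence, so
their sequence direction is flipped to keep every axis pointing
extracellular.  Spin is positive for a right-handed rotation about that
axis carrying structure A onto structure B; swapping the structures negates
spin and axial translation and preserves tilt.

# The synthetic generator: what it does and does not emulate

`make_bundle()` arranges seven ideal α-helices (1.5 Å rise, 100°/residue)
on a ring, with a Cβ pseudo-atom 1.5 Å radially outside each non-glycine Cα
standing in for side-chain bulk.  Defaults are chosen to match the study
conditions the analyses assume: 26-residue helices (a typical annotated TM
length) and a ring radius of 6.5 Å, which yields on the order of 200
inter-helical contacts per bundle — the density real receptor structures
show.  Because the proxy has only two heavy atoms per residue, reaching that
density requires a tighter ring than a real bundle; the closest atom pairs
then approach below van-der-Waals separation, which is physically
impossible but irrelevant to every threshold-based computation under test.
What the generator does *not* emulate: side-chain rotamers and packing,
helix kinks (notably the proline kinks of TM6/TM7), loops, and membrane
physics.  Passing tests therefore demonstrate the correctness of the
*algorithms* — contact counting, anchor recovery, decomposition,
clustering — not the biological accuracy of any particular alignment;
the published-data regressions exist for that and require the published
inputs.

`make_family()` mutates ancestor sequences site-independently with a fixed
substitution probability (default 0.1 per site, uniform over the other 19
residues), giving within-family similarities well above between-family ones
so that clade recovery has a defined ground truth.  Real families violate
site-independence; nothing downstream depends on it beyond the similarity
gap.  All generators are deterministic per seed and restore the caller's
RNG state.

# Numerical choices and degenerate inputs

* Altloc collapse keeps the highest-occupancy copy, ties to the
  alphabetically first altloc; zero-occupancy atoms are dropped; hydrogens
  are dropped at load time; modified residues map to parents (MSE→M etc.);
  non-standard residues are dropped with a warning.
* A residue with no heavy atoms is skipped with a warning, not an error —
  unresolved side chains are routine in crystal structures.
* TM-range extension by helix labels grows cores outward while the DSSP
  label stays `H` and stops before touching a neighboring core, which keeps
  the seven ranges disjoint and makes the operation idempotent.
* `fit_axis()` refuses fewer than 4 residues and collinear geometry.
* `compare_states()` with identical panels returns empty changed sets; the
  three contact categories are disjoint by construction.
* Percentages in summaries are rounded to 1 decimal at the reporting
  boundary only; scores and similarities are never rounded internally.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic inputs:
bundles of 7×18–26 residues (≈150–220 contacts), anchor searches over ±4
windows for all 56 single-helix shifts, similarity matrices and UPGMA trees
over 32 sequences (4 families × 8 members), and variant cohorts of 60–400
substitutions.  These sizes keep every oracle (brute-force contact
enumeration, double-loop similarity, closed-form quaternion superposition)
cheap enough to run exhaustively while leaving all code paths identical to
full-scale use; the published-scale analyses (24-structure class-A panels,
817-protein trees) run through exactly the same functions when the
corresponding tables are supplied.

# Known limitations

* Gapless helices are an axiom, not a finding: receptors whose TMs genuinely
  bulge relative to the template family are forced into registry.
* Coordinate ascent can in principle miss jointly-coupled optima outside the
  joint mode's practical window.
* The NACHO criterion is all-or-none over a small number of structure pairs;
  with larger panels the tolerant parameters should be preferred.
* The variant score is a heuristic prioritization, not a calibrated
  pathogenicity probability; its substitution term uses the raw matrix entry
  with no weighting against the distance terms.
* DSSP output is consumed, never computed: secondary structure must come
  from outside, and the TM annotation CSV is the source of truth, including
  any manual corrections a curator makes to it.
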
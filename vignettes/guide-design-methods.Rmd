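---
title: "Designing species-discriminating Cas12a guides on DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing species-discriminating Cas12a guides on DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cas12a coupled to isothermal pre-amplification (RPA) makes a fast,
field-deployable species-authentication assay: amplify a short DNA barcode
locus (for plants, typically chloroplast *trnL*, a few hundred nt), add
Cas12a loaded with a crRNA designed against the target species' barcode,
and read out collateral (trans) cleavage of a quenched ssDNA reporter as
fluorescence. The assay is only as good as the guide: a crRNA whose
protospacer and PAM are conserved across relatives lights up for
everything, while a well-placed guide is positive only for the target
species.

`crisprbarcode` implements the computational side of that design problem:
given species-labelled barcode sequences, it aligns them, scans the target
for Cas12a PAM sites, measures how each candidate protospacer differs in
every other species, predicts the qualitative per-species readout, and
ranks candidates by discrimination power. It also locates RPA primers and
predicted amplicons, emits T7 in-vitro-transcription constructs, and
scores blinded panels with confusion-matrix accuracy and precision.

## Discrimination model

Two properties of a candidate site carry the species signal:

1. **PAM variation.** Cas12a requires a `TTTV` PAM (V = A, C or G)
   immediately 5' of the protospacer. Per non-target species the PAM
   window is classified `canonical` (matches the pattern under IUPAC
   set-intersection semantics), `variant` (present but pattern-breaking),
   or `absent` (an alignment gap falls in the window — the species lacks
   the site altogether).
2. **Spacer mismatches.** Mismatches between the candidate spacer and the
   orthologous window of another species are counted separately in the
   **seed** region (spacer positions 1–5, numbered from the PAM-proximal
   base) and the **distal** remainder. Seed mismatches are the strongest
   activity killers; distal mismatches are better tolerated. An alignment
   gap inside the spacer counts as a mismatch at that position and is also
   reported in `gap_positions`.

The qualitative call for a species is produced by a small penalty model
(`activity_rules()`):

```
score = seed_penalty * seed_mm + distal_penalty * distal_mm
        + pam_variant_penalty * [PAM variant]
call  = negative  if PAM absent
        positive  if spacer identical (identity override)
        positive  iff score < threshold, otherwise negative
```

Rule order matters and was a genuine design decision: an absent PAM is
checked **before** the identity override, because without a PAM Cas12a
cannot license binding no matter how perfect the spacer match is. The
identity override exists for the converse case — a *variant but present*
PAM with a perfectly conserved spacer can still trigger cleavage, which is
exactly how a non-target relative can produce a false positive on a real
panel. It can be switched off (`identity_override = FALSE`).

Two presets ship, because published observations pull in two directions:
seed mismatches are commonly described as near-intolerable, yet conserved
sites with a single seed-position-2 variant have been observed to stay
positive in all species. `strict` (`seed_penalty = 3`, `threshold = 3`)
makes any seed mismatch negative on its own; `permissive`
(`seed_penalty = 2`, `threshold = 4`) lets a single seed mismatch with a
canonical PAM stay positive. The presets expose, rather than resolve, this
empirical ambiguity; `strict` is the default because design advice should
treat the seed as fragile. The numeric penalty values are calibration
choices of this package, not measured constants.

Candidates are ranked by the fraction of off-target species called
negative (the target itself must be positive, or the candidate is
disqualified). Ties break deterministically: larger total off-target
penalty, then fewer off-target canonical PAMs, then leftmost window, then
input order.

## Alignment

Barcode loci are short, so the package carries its own deterministic
aligner rather than shelling out to an external MSA tool: global pairwise
Needleman–Wunsch (match +1, mismatch −1, linear gap −2; traceback ties
resolved diagonal → up → left) feeding a center-star multiple alignment
(center = record with maximal summed pairwise score, first wins ties;
merging follows "once a gap, always a gap"). Equivalence with any
particular external aligner's output is explicitly not claimed; users who
prefer MAFFT or similar can load gapped FASTA via `read_barcode_fasta()`
and `as_barcode_msa()`, which bypasses alignment entirely.

Coordinates are 0-based half-open internally (`msa_project()` /
`msa_residue_at()` map residues to columns and back); printed reports use
1-based positions. When a species has several records they are collapsed
column-wise to an IUPAC consensus (union of base sets) before assessment;
a column where any record of the species is gapped is treated as a gap,
which is the conservative choice for PAM-absence calls. Candidate windows
interrupted by a gap column in the target row, and windows at which
duplicate target records disagree, are excluded.

## RPA amplicon checks

`locate_primer()` slides each primer (reverse primer as its reverse
complement) along the template counting IUPAC-aware mismatches; the
default tolerance of 2 mismatches per primer reflects RPA's known
leniency and is configurable. `predict_amplicon()` pairs every forward
site with every downstream reverse site (up to 1500 nt) and reports the
product *including both primer footprints* — the length a gel would show.
A guide is "contained" only if its whole PAM+spacer window lies strictly
between the footprints; in `evaluate_panel()` a sample whose amplicon
does not contain the guide is forced negative.

## Panel evaluation

`confusion_matrix()` scores a binary authentication panel: TP/FN are
target samples called positive/negative, FP/TN the non-target
counterparts. Accuracy is correctly-predicted over total samples × 100;
precision is true target among predicted-target × 100; recall (reported
for completeness) is 100·TP/(TP+FN). Percentages are rounded half-up to
two decimals to match reporting conventions; an undefined precision
(nothing called positive) is reported as `NA`, deliberately distinct from
0.00.

## The synthetic generator and what passing tests mean

`generate_panel()` builds a random target locus (default 400 nt, uniform
ACGT), plants a concrete PAM+spacer window at a chosen position and
strand, and derives each off-target species by applying the exact edits
listed in the `panel_spec()` — substitutions or gaps placed in the PAM,
seed, or distal zone of the planted window — plus uniform background
substitutions outside the window (default 2 % per site, of the order of
intra-genus barcode divergence). Because every within-window difference is
placed deliberately, the generator knows the assessment each species must
receive and returns it as ground truth: the construction is its own
oracle.

Two generator properties are worth stating explicitly:

* **Window exclusivity.** After planting, any pattern-compatible PAM frame
  (either strand) whose PAM+spacer window overlaps the planted window is
  broken by a single substitution outside the planted PAM. Overlapping
  frames share the planted discriminating edits — and can even extract
  *more* penalty from them (a PAM-zone substitution scores as a seed
  mismatch in an overlapping frame but only as a PAM variant in the
  planted one) — so without this step the "planted, target-exclusive
  site" premise would not actually hold.
* **Recovery dominance.** The recovery benchmarks give every off-target a
  variant PAM plus three seed mismatches (penalty 2 + 3·3 = 11 per
  species under `strict`). Any non-overlapping window can collect at most
  background-level penalties, so the planted site wins the
  total-penalty tie-break whenever discrimination fractions tie; this is
  a provable margin, not a tuned one.

Indels default off so window assessments are exactly checkable without
alignment ambiguity; gap edits (used to model an absent PAM) are written
directly into the returned ground-truth alignment, so fixtures do not
depend on the aligner reconstructing an ambiguous indel placement.

What the generator does **not** emulate: phylogenetic structure
(substitutions are i.i.d., not tree-distributed), rate heterogeneity,
real indel processes, sequencing error, or intra-species haplotype
diversity (panel samples replicate their species sequence exactly).
Passing tests therefore demonstrate the correctness of the scanning,
assessment, ranking and evaluation machinery under controlled variation —
not that any particular guide will behave as predicted on real DNA, where
enzyme kinetics and the unmodelled sequence features above intervene.

## Named fixtures

Three fixtures encode described assay configurations with synthetic
sequences (they are layout-faithful, not biological reference data):
`"gRNA-A"` (target-exclusive PAM; off-targets with variant PAM + seed
mismatch, variant PAM + three distal mismatches, and absent PAM — target-
only positive under `strict`), `"gRNA-B"` (canonical PAM everywhere, a
single seed-position-2 variant — all-positive under `permissive`), and
`"accuracy-panel"` (20 samples: 7 target, 13 non-target across eight
species, two of which carry a variant PAM with an identical spacer and
are therefore false positives via the identity override, giving
TP 7 / FP 2 / TN 11 / FN 0, accuracy 90.00 %, precision 77.78 %,
recall 100 %).

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on generated data:
loci of 300–500 nt, panels of 4–9 species, 100 recovery panels, 200
random pairs for alignment-oracle checks and 100 random sequences for
each sliding-window oracle. These sizes exercise every code path at the
scale the method targets (short barcode loci) while keeping the suite
fast. All randomness is seeded; `generate_panel()` restores the caller's
RNG state. The aligner's scoring is exact integer arithmetic in C++;
there are no tolerances anywhere in the core model. Degenerate inputs are
defined rather than left to chance: empty sequences align against
all-gaps, a sequence shorter than PAM+spacer yields an empty (warned)
hit list, a single-record panel returns a trivial alignment with a
warning, and an empty candidate list is an empty report, not an error.

## Limitations

* The activity model is qualitative and rule-based; it predicts calls,
  not fluorescence intensities, kinetics, or detection limits.
* Penalty values and the negative threshold are package calibration
  choices; users with assay data for their system should fit their own
  `activity_rules()`.
* Center-star alignment with linear gaps is adequate for short,
  mostly-colinear barcode loci but is not a general-purpose MSA.
* Amplicon prediction is positional only — no thermodynamics, no
  primer-design scoring.
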
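---
title: "Scoring plastome indels and testing outgroup sensitivity"
author: "plastgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring plastome indels and testing outgroup sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastgap)
```

## The problem

Whole plastid genomes are routinely aligned across tens of taxa to resolve
relationships that single loci cannot.  Two pieces of information in such
alignments are usually handled ad hoc: (a) the gap structure — insertions
and deletions that, when scored carefully, are near-irreversible characters
carrying their own phylogenetic signal — and (b) the sensitivity of the
inferred ingroup topology to which outgroup genomes happened to be chosen.
plastgap makes both analyses scripted and reproducible, together with the
matrix-construction bookkeeping (inverted-repeat removal, inversion
excision, gap-column stripping) that precedes model-based inference.

Throughout the package, alignment columns are numbered **1-based with
closed intervals**, the R/Bioconductor convention; GFF3 input needs no
coordinate shift.

## Indel scoring model

A multiple alignment over `{A,C,G,T, IUPAC, N, -}` is scanned for maximal
gap runs per row.  Runs with an *identical* column footprint are merged
into one candidate event: under the assumption that an identical shared gap
is a single evolutionary event, the taxa sharing it inherited one indel.
Four acceptance rules then apply, in a fixed order so that reports are
deterministic (first failure is recorded):

1. **too_short** — events must be at least `min_length` (default 2) bp.
2. **mononucleotide** — a homopolymer segment whose immediately adjacent
   base matches is excluded *regardless of length*: single-base repeats
   expand and contract so freely that homology of individual copies is
   meaningless.
3. **ambiguous_overlap** — events whose footprints partially overlap
   (including nested) are rejected on both sides; only cleanly identical
   or disjoint footprints are interpretable as single events.
4. **autapomorphic** — events present in fewer than `min_shared`
   (default 2) rows are not scored; a gap confined to one row supports no
   grouping.

Terminal gap runs (touching the first or last column) are treated as
missing data — truncated sequence ends, not indels — and never become
events.

**Slipped-strand mispairing.**  Replication slippage at a repeat inserts
or deletes one repeat copy, so an SSM indel is diagnosed by a perfect or
near-perfect copy of the indel segment in the immediately adjacent flank.
The segment is read from the ungapped rows (per-column majority vote, ties
resolved by first taxon order) and compared with the equal-length windows
ending at the event start and beginning at the event end.  An exact match
is `perfect`; best identity at or above `ssm_identity_threshold` is
`near_perfect`; otherwise `none`.  The default threshold of 0.80 is a
package choice — "near-perfect" has no universal operationalization — and
is configurable.  Only equal-length immediately adjacent windows are
examined; longer-period repeats are out of scope.

**Region classes.**  With a GFF3 annotation on alignment coordinates,
events are classed `coding` (CDS), `intron`, or `igs` (the spans between
annotated features).  The class with maximal column overlap wins; ties go
by the precedence coding > intron > igs, so an event straddling an
exon/intron boundary counts as coding.

## Mapping indels on a tree

Each accepted event becomes one binary character: state 1 where the gap is
present (segment absent), state 0 where the segment is present, missing
(`NA`) for rows that are entirely `N`/ambiguous across the event.  No
insertion/deletion polarity is asserted at cataloguing time; polarity
comes from the outgroup at mapping time.  Characters are never used in
tree *search* — they are mapped a posteriori onto a reference topology.

The derived state is the state opposite the outgroup's (consensus over
outgroup rows); when the outgroup is missing or conflicting, the minority
ingroup state is used, with ties resolved to state 1 — a documented
heuristic, since gaps are more often derived than retained segments.
A character whose derived leaves number ≥ 2 and form a clade is a putative
synapomorphy for exactly that clade; this is equivalent to requiring a
single state change when the root is constrained to the ancestral state.
Characters needing two or more changes are putative homoplasy.  Characters
invariant among scored ingroup rows are excluded, and single-leaf derived
sets are flagged `autapomorphic` (they cannot arise if the catalogue
criteria were applied upstream, but the classifier reports rather than
assumes).

The step count itself (`fitch_steps`) is a unit-cost small-parsimony
dynamic program over per-node cost vectors.  Unlike textbook Fitch set
operations it is exact on multifurcating trees, and missing leaves carry
zero cost for both states, contributing no constraint.  The count is
invariant under rerooting; the test suite verifies it against exhaustive
enumeration of all internal-state assignments on trees of up to 10 leaves
and against an independent parsimony implementation.

`tabulate_clades` counts synapomorphies per *named* clade by exact
leaf-set equality (not compatibility), lists unmatched synapomorphies
under their literal leaf sets rather than guessing, and reports the
homoplasious total as its own row.  Indels shared by a clade *plus* the
outgroup polarize to ingroup-invariant and are excluded rather than
ascribed to the ingroup complement; they appear in the classification
table as `invariant_excluded`, where they can be inspected.

## The outgroup jackknife

The experiment asks: does the ingroup topology depend on which outgroup
representatives were used?  From named pools of candidate outgroups (one
pool per donor lineage), each iteration draws one representative per pool
uniformly at random, re-infers the tree, prunes the outgroups, and the
pruned ingroup topologies are compared across iterations by unrooted
Robinson–Foulds distance (`all_identical` when every pairwise distance is
zero), with a strict consensus and a per-node support summary: mean and
sample (n−1) standard deviation of bootstrap support across the
iterations in which the node occurs.

The built-in backend computes Jukes–Cantor distances with pairwise
deletion, a neighbor-joining topology, and nonparametric bootstrap
supports from seeded column resampling — chosen so the experiment runs in
seconds at desk scale.  Maximum-likelihood inference is deliberately *not*
reimplemented; `run_iteration` accepts a backend function so an external
ML program can be wrapped, its tree read back in, and the rest of the
machinery reused unchanged.

Reproducibility rules: outgroup draws for iteration *i* are seeded by
`seed + i`, so any iteration can be regenerated in isolation; the backend
RNG is seeded from the master seed and the *selected taxon set*, so
identical inputs yield identical trees and supports regardless of
iteration index.  The latter guarantees the degenerate case — singleton
pools with the deterministic backend — reports RF 0 and a support standard
deviation of exactly 0 at every node.  Draws are independent across
iterations (sampling with replacement across iterations); 16 iterations is
the conventional default.

## The synthetic-data generator

Every stage is testable offline because the generator produces data with
the statistical structure the analysis assumes, plus ground truth:

* **Tree** — pure-birth (Yule) construction: with *k* lineages the next
  split waits Exp(*k*·birth), giving contemporaneous tips and expected
  root height (1/λ)·Σ<sub>k=2..n</sub> 1/k, which the tests check by
  Monte Carlo.
* **Sequences** — HKY substitution (default κ = 3, slightly AT-rich base
  frequencies as in plastomes) with 4-category discrete-gamma rate
  heterogeneity, at an overall rate in expected substitutions per site per
  unit branch length.
* **Indels** — a Poisson number of events per branch (default mean 1.6,
  about 60 events on a 20-taxon tree), geometric lengths with minimum 2
  (default mean ≈ 3.9 bp), a configurable SSM fraction (default 0.47,
  matching the roughly half of scored plastome indels attributable to
  slippage) split between insertions and deletions, and a mononucleotide
  fraction (default 0.10) exercising the homopolymer exclusion.  Events
  are inherited by all descendants of their branch and placed without
  overlap by rejection sampling with generous separation, so the
  identical-footprint clustering assumption holds by construction.
* **Annotation** — the alignment is tiled into coding/intron/igs features
  (mean length 600 columns, mixture 0.45/0.10/0.45); igs spans are the
  complement of annotated features, so the annotation round-trips through
  GFF3 where igs is implicit.
* **Missing data** — a fraction of taxa (default 0.15) receive a truncated
  terminal stretch of up to 150 columns, emulating partial assemblies.

Ground-truth guarantees at substitution rate 0: SSM insertions are exact
tandem copies of their (forced-identical) upstream flank; SSM deletions
remove one copy of a duplicate planted in the background; plain events are
rejection-sampled until both flanks fall below the detection threshold by
a margin; mononucleotide events extend a homopolymer whose adjacent base
matches; SSM motifs are never homopolymers (a one-base tandem repeat *is*
a mononucleotide repeat, which the criteria must reject).  Under these
conditions the catalogue recovers every eligible event exactly — interval,
taxon membership and SSM label — which is what the acceptance suite
asserts.  A `flank_noise` stress mode sprinkles substitutions into the
repeat copies to degrade identity below threshold for negative tests.

What the generator does **not** emulate: realistic gene content and IR
structure, alignment error, post-duplication divergence of repeat copies
at nonzero rates (flank columns are forced identical at injection time),
and content evolution *within* inserted segments.  Passing tests therefore
demonstrate the correctness of the scoring and mapping machinery, not the
behaviour of MAFFT-style alignment on real plastomes — on real data the
"unambiguous" adjudication of overlapping or shifted gaps remains the
dominant source of disagreement between any two scorers, which is why the
catalogue exposes per-criterion rejection counts.

## Numerical and design choices

* Ambiguity codes and `N` are treated as missing for pairwise comparison
  and character coding but never trigger gap-column removal — only `-`
  does.  `?` is normalized to `N`; the `.` match-character dialect is
  rejected.
* Pairwise percent difference/identity is computed over columns where both
  rows have an unambiguous base, and the compared-column count is always
  reported alongside the percentage.
* Rejection reasons are evaluated in the fixed order documented above;
  `summarize_catalog` satisfies accepted = total − Σ rejected-by-reason.
* Inversion regions and the duplicated IR copy are supplied as explicit
  column intervals; the package does not attempt to detect them.
* Sample (n−1) standard deviation is used for the support summaries.
* Desk-scale problem sizes used by the tests and the acceptance script:
  indel recovery on 20 taxa × 20 kb (substitution-free); parsimony
  checked exhaustively on 200 random trees of ≤ 10 leaves × 20 characters;
  the jackknife on 14 taxa × 12 kb at rate 0.06 with 16 iterations and 100
  bootstrap replicates.  The 12 kb length is chosen so that internal
  branches of a random Yule tree carry enough expected substitutions for a
  distance method to resolve them stably — shorter simulations probe the
  noise floor of the generator, not the congruence machinery; real
  plastome matrices are an order of magnitude longer.

## Known limitations

* The built-in backend is distance-based; bootstrap supports are not
  comparable in absolute terms to maximum-likelihood bootstrap values,
  though their *variability across outgroup draws* — the quantity the
  experiment measures — behaves analogously.
* SSM detection considers only the two immediately adjacent equal-length
  windows; slippage at longer-period or interrupted repeats is not
  diagnosed.
* Clade tabulation uses exact leaf-set equality; paraphyletic "grades"
  must be queried through the classification table.
* Exact reproduction of manually curated indel counts from published
  matrices is not guaranteed under any fixed rule set, because published
  scoring typically involved by-eye adjudication of ambiguous cases; the
  per-criterion rejection counts are the diagnostic surface for such
  comparisons.
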
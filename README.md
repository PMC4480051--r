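# plastgap

Tools for the bespoke computational steps of whole-plastome phylogenomics
in R: building analysis matrices from plastome alignments, scoring indels
as discrete evolutionary events with slipped-strand-mispairing (SSM)
detection, mapping indel characters onto a reference tree as putative
synapomorphies or homoplasy, and testing whether the ingroup topology is
robust to randomized outgroup choice.  A seeded simulator generates
clock-like trees, plastome-like sequences and ground-truth indel events so
the whole pipeline runs and is testable with no external data.

## Who this is for

Plant systematists working with plastid genome alignments (typically
130–160 kb matrices arranged LSC + IRb + SSC over tens of taxa) who want
the steps *around* tree inference to be scripted, reproducible and
auditable: which alignment columns entered the analysis, which gaps were
scored as indels and why, which indels support which clades, and whether
the ingroup topology depends on which outgroup representatives were drawn.

## What it computes

**Matrix construction.**  One inverted-repeat copy and any
inversion-bearing regions are excised as user-supplied column intervals;
every column containing a gap in at least one row is then removed
(`strip_gap_columns`), with full column provenance (`column_map`) and a
report of the fraction removed.  All coordinates are 1-based, closed.

**Indel scoring.**  Maximal gap runs per row are clustered by identical
column footprint — a shared footprint is interpreted as a single
evolutionary event.  Events are accepted only if they

1. are ≥ 2 bp long, excluding mononucleotide repeats regardless of length
   (a homopolymer gap whose flanking base matches is rejected),
2. are unambiguous: footprints that partially overlap another event are
   rejected on both sides,
3. are shared by ≥ 2 rows (autapomorphies are not scored).

Accepted events are assessed for SSM by comparing the ungapped segment
with the equal-length windows immediately up- and downstream: an identical
window is a `perfect` tandem repeat, identity ≥ 0.80 (configurable) is
`near_perfect`, otherwise `none`.  With a GFF3 annotation, each event is
assigned `coding` / `intron` / `igs` by maximal overlap with precedence
coding > intron > igs.

**Tree mapping.**  Each accepted indel becomes a binary character
(1 = gap/segment absent).  On the reference tree rooted with the outgroup,
the derived state is the state opposite the outgroup's; a derived set of
two or more leaves forming a clade is a putative synapomorphy for that
clade (equivalently, one change under Fitch parsimony with that polarity),
two or more changes is putative homoplasy.  The step count is an exact
unit-cost small-parsimony dynamic program that handles missing states and
multifurcations.  `tabulate_clades` produces the per-clade count table.

**Outgroup jackknife.**  Given named pools of candidate outgroups, each of
`n_iterations` (default 16) draws one representative per pool, re-infers
the tree (built-in backend: Jukes–Cantor distances, neighbor joining,
nonparametric bootstrap over columns; an external ML backend can be
plugged in as a function), prunes the outgroups, and finally reports all
pairwise Robinson–Foulds distances between ingroup topologies, an
`all_identical` flag, and the mean ± sample standard deviation of
bootstrap support per ingroup node across iterations.

## Worked example

A five-row toy alignment in which the two *Melica* individuals share a
3-bp deletion at columns 6–8, right after an `ATG` that tandemly repeats:

```r
library(plastgap)

aln <- multiple_alignment(c(
  Brachyelytrum = "CCATGATGTTCCGAATTGGCAGTTA",
  Melica_1      = "CCATG---TTCCGAATTGGCAGTTA",
  Melica_2      = "CCATG---TTCCGAATTGGCAGTTA",
  Stipa         = "CCATGATGTTCCGAATTGGCAGTTA",
  Oryza         = "CCATGATGTTCCGAATTGGCAGTTA"))

ev <- indel_catalog(aln)
as.data.frame(ev)
#>   event start end length n_taxa   status reject_reason     ssm     region
#> 1     1     6   8      3      2 accepted          <NA> perfect unassigned
```

The event is accepted (3 bp, shared by two rows, no overlap), and the
segment `ATG` exactly matches its upstream flank, so it is attributed to
slipped-strand mispairing (`perfect`).  Mapping it on a reference tree
rooted with *Oryza*:

```r
m  <- build_character_matrix(ev, aln)
tr <- ape::read.tree(text =
  "(((Brachyelytrum,(Melica_1,Melica_2)),Stipa),Oryza);")
classify_characters(tr, m, outgroup = "Oryza")
#>   character_id fitch_steps        status derived_state   supported_clade
#> 1       indel1           1 synapomorphic             1 Melica_1,Melica_2

tabulate_clades(classify_characters(tr, m, outgroup = "Oryza"),
                list(Meliceae = c("Melica_1", "Melica_2")))
#>                 clade n_taxa indels
#> 1            Meliceae      2      1
#> 2 Homoplasious indels     NA      0
```

The single scored indel arose once, on the branch subtending the two
*Melica* rows: one putative synapomorphy for Meliceae, no homoplasy.
Gap-column stripping on the same alignment removes the three gapped
columns:

```r
strip_gap_columns(aln)$report
#> $n_before 25   $n_after 22   $fraction_removed 0.12
```

A command-line wrapper with subcommands `preprocess`, `indels`, `map`,
`jackknife` and `simulate` is installed as `exec/plastgap`.

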
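---
title: "Methods: subfamily residue signatures and gene-neighbourhood analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subfamily residue signatures and gene-neighbourhood analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetzkit)
```

cetzkit characterises protein subfamilies — its motivating case is the
archaea-specific CetZ family of tubulin-superfamily cytoskeletal proteins,
whose CetZ1 and CetZ2 subfamilies in Halobacteria are implicated in rod-shape
development and motility — through three complementary computations:

1. **Discriminating ("unique") residues** between two groups of aligned
   sequences, from per-group consensus profiles;
2. **Gene-neighbourhood conservation and synteny** around focal genes, using
   arCOG orthologous-group labels, including detection of type IV pili
   regulon cassettes;
3. **Co-occurrence tallies** of subfamily presence with reported phenotypes
   across species.

A seeded synthetic-data module generates inputs with known ground truth for
all three, and `run_pipeline()` wires the stages together.

## Consensus profiles and unique residues

For a group $g$ and alignment column $c$, the *consensus score* is

$$ S_g(c) = 100 \times \frac{\max_r n_{g,c}(r)}{d_{g,c}}, $$

where $n_{g,c}(r)$ counts non-gap characters equal to residue $r$ and
$d_{g,c}$ is the column depth (non-gap count). The *unique residue score*
of a column for groups $a$ and $b$ is the arithmetic mean
$U(c) = (S_a(c) + S_b(c))/2$, and a column is called a unique residue when
the two consensus residues differ and $U(c)$ strictly exceeds the threshold.

Assumptions and numerical choices:

* **One joint alignment.** Both groups must live in a single alignment with
  group labels, so column correspondence is explicit. Comparing columns
  across two independently built alignments is ill-defined without a column
  mapping; requiring a joint alignment is the minimal well-defined
  formulation. Group labels are free strings — nothing is hard-coded to
  particular subfamily names.
* **Gaps** are excluded from both numerator and denominator of the consensus
  score, and columns where either group is more than 50% gapped are excluded
  from calling (`max_gap_fraction`, configurable): a majority-gap column has
  no meaningful consensus. An all-gap column has no consensus residue and
  score 0.
* **Ambiguity codes** `X`/`B`/`Z` count toward depth but are never eligible
  as consensus residues, because they cannot be chemistry-classified.
* **Ties** on the modal residue are broken alphabetically and flagged in the
  profile, for determinism.
* **Strict inequality** (`> threshold`) is the default calling rule, with a
  `strict = FALSE` switch for `>=`. The customary thresholds are 90 for
  subfamily-level comparisons and 80 for family-level ones
  (`threshold_pct`, in percent).
* **Requiring differing consensus residues** is part of this package's
  definition of a unique residue; a column where both groups conserve the
  same residue is conserved, not discriminating.
* **Chemistry classes** default to a five-class side-chain scheme
  (nonpolar G A V L I M P; aromatic F W Y; polar uncharged S T C N Q;
  positive K R H; negative D E) and are overridable via
  `chemistry_classes()` or a TSV, since published colour schemes rarely pin
  the classes down. A different class scheme changes only the
  similar/different labels, never which columns are called.

`shared_unique_residues()` scores a query row against one side's consensus
residues over a call set (a gap never matches); `region_lengths()` profiles
ungapped spans, e.g. the M-loop region that is long (around 14–26 residues)
in CetZ1-like proteins and short (around 3–6) in CetZ2-like ones.

## Gene neighbourhoods

`extract_neighborhood()` takes the window from `focal_start - flank_bp` to
`focal_end + flank_bp` — the flank (default 20 000 bp, i.e. a 40 kb
neighbourhood plus the gene) is measured from the gene boundaries, not from
the gene midpoint, matching how such regions are drawn in genome maps. The
window is clipped at linear contig ends and wraps across the origin of
circular contigs (represented as two intervals; circularity is declared in
the contig table, never guessed). Genes partially overlapping the window are
included whole: the tallies count genes, not base pairs. Coordinates are
1-based inclusive throughout (the GFF3 convention) and are never silently
converted.

`tally_arcogs()` reports two deliberately separate statistics per arCOG:
*occurrences* (total genes across regions — a region can contribute more
than one, e.g. when a second subfamily gene lies inside the window) and
*presence* (number of regions containing at least one).
`conserved_arcogs()` thresholds presence at an absolute count, defaulting to
a majority (`ceiling(n/2)`); the threshold used is always attached to the
output and echoed in pipeline headers, because published analyses are not
always consistent about whether "conserved" means a majority or a fixed
count.

**Pili regulon classification.** A `regulon_definition()` names anchor
arCOGs — the pilB ATPase (arCOG01818) and the pilC membrane platform — plus
accessory pilin arCOGs (default: arCOG05787, 05789, 03821, 03822, 05790,
05786, 05788). The pilC arCOG id must be supplied by the user because no
standard identifier is bundled; synthetic cassettes in the test suite use a
clearly synthetic stand-in id (`arCOG90001`). A region is pili-associated
when it contains at least `min_anchors` (default 2, i.e. both pilB and pilC;
accessory pilins alone never trigger association) distinct anchors and all
matched regulon genes form a run interrupted by at most `max_gene_gap`
(default 3) consecutive non-regulon genes. "Adjacent" is not quantitatively
defined in the literature this mirrors; the run/gap rule is one defensible
operationalisation, and unassigned genes conservatively count as
interruptions. `genome_wide_arcog_placement()` extends this to a
whole-genome question, classifying a target arCOG as `in_focal_region`,
`elsewhere_with_regulon` (within `flank_bp` of enough distinct anchors),
`elsewhere_alone`, or `absent`, returning the first matching category in
that order.

**Synteny.** `synteny_table()` reports each member gene at a signed bp
offset from the focal gene with the focal gene oriented left-to-right;
regions whose focal gene is on the minus strand are mirror-reflected so
maps are comparable across species. arCOGs outside the conserved set
collapse to `"other"`, unassigned genes to `"unassigned"`.

## Co-occurrence tallies

`tally_cooccurrence()` enumerates a species table into subfamily marginals
(both, CetZ1-only, CetZ2-only, neither) and phenotype intersections
(motility reported, rods reported). A species lacking a phenotype report is
*not* treated as negative evidence — the flags record reports only — which
is why no significance test is attached to these counts: the sampling
process behind "reported" is uncontrolled. `crosstab()` gives raw 2×2
tables for any pair of boolean fields.

## The synthetic-data generators

The generators define the package's study conditions; their defaults are
fixed once and the validation suite is run against them.

* `simulate_subfamily_alignment()` emulates a two-subfamily joint alignment:
  group sizes default to the 49 + 41 split typical of curated CetZ1/CetZ2
  sets, planted discriminating columns give each group its own residue at a
  stated conservation (1.0 in the headline condition), and background
  columns share one modal residue across both groups at conservation 0.5
  with a 2% per-cell gap rate. Sharing the background modal residue across
  groups makes the null explicit: background columns can only produce a
  false call through sampling noise, so the false-positive behaviour of the
  caller is measurable. What it does *not* emulate: phylogenetic
  correlation between sequences, indel structure, or any substitution
  model — a perfect score on synthetic data shows the counting and calling
  machinery is exact, not that real subfamilies separate this cleanly.
* `simulate_genomes()` emulates annotated archaeal genomes: one focal gene
  per genome (arCOG02202, the tubulin-family arCOG, by default), gene
  lengths uniform on 600–1500 bp and intergenic gaps on 50–400 bp (dense,
  prokaryote-like packing), a core pool of arCOGs planted inside the window
  either probabilistically (`retention_prob`) or exactly (`n_present`,
  `n_double` — needed because published occurrence/presence tallies are
  exact counts, not expectations), an optional pili cassette inserted
  contiguously adjacent to the focal gene in carrier genomes (or distally,
  to exercise the placement categories), and unique filler arCOGs in the
  remaining window slots plus a few genes outside the window. Half the
  contigs are circular by default so origin-wrapping is routinely
  exercised. Filler genes fill all free window slots rather than a fixed
  count, emulating dense genomes; `n_distal_genes` controls background
  genes outside the window.
* `simulate_species_table()` constructs a phenotype table whose tallies
  equal planted counts *exactly* (deterministic construction; the seed only
  shuffles row order and the uninformative other-CetZ column). The bundled
  55-species condition (45 both / 7 CetZ1-only / 3 neither; 40 rods of
  which 37 both + 2 CetZ1-only; 26 motile of which 24 both + 1 CetZ1-only)
  reconstructs the published Halobacteria tabulation from its printed
  counts, standing in for the appendix table that is not redistributed with
  the package.

All generators are bit-reproducible given their spec (seeding is scoped via
`withr::with_seed`, so user RNG state is untouched).

## Validation problem sizes

The test suite checks the implementation against independent brute-force
oracles (direct per-column counting for consensus; a doubled-/tripled-
coordinate interval scan for circular windows) at these scales, chosen to
exercise the combinatorics while keeping the default suite quick: 100
random alignments up to 50 × 500 for oracle equivalence; 200 random genomes
(half circular, 60 kb contigs so that wrap cases are frequent) for window
membership; 100 replicates of the 20-genome, 12-core-arCOG retention-0.9
condition for conserved-set recovery; and the exact 20-region and 22-region
tally conditions described above. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the resulting numbers as JSON.

## Known limitations

* One arCOG per locus: multi-assignment resolution is left to upstream
  preparation of the assignment table.
* The cassette rule classifies a region as non-associated if a stray
  accessory pilin lies far from an otherwise intact cassette (the "single
  run" reading); real annotations with duplicated pilins may need a wider
  `max_gene_gap`.
* GenBank flat files are not parsed; convert to GFF3 or the feature-table
  TSV dialect first. Trees are neither built nor consumed — subfamily
  membership enters only through the group-label table.
* The chemistry split of a call set depends on the class scheme; with
  user-overridden classes the similar/different proportions will differ
  from the defaults.
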
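---
title: "Methods: comparative plastome analysis and super-barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis and super-barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superbarcode)
```

## The problem and the model

Species identification from short standardized loci (DNA barcoding) fails
for recently radiated plant genera: the core plastid barcodes *matK* and
*rbcL*, the *trnH–psbA* spacer, and nuclear ITS can each carry only a
handful of variable sites across an entire genus, leaving some species
pairs with zero diagnostic SNPs. Whole chloroplast genomes ("super-
barcodes") sidestep this: at a genome-wide divergence of only 0.1–0.6%,
a ~152 kb plastome still separates every species pair by hundreds of
substitutions.

The quantities this package computes are deliberately model-free. Pairwise
divergence is the raw count of alignment columns in which two taxa both
carry an unambiguous residue (A/C/G/T) and the residues differ; columns
with a gap or N in either row never contribute. No distance correction
(JC, K2P) is applied: at these divergences multiple hits are negligible
(p < 0.006 implies an expected correction below 2 × 10⁻⁵ per site) and raw
counts are what published plastome comparisons print. Trees are built by
canonical neighbor joining on `counts / denominator`; clade confidence
comes from resampling alignment columns with replacement (bootstrap) and
counting how often each full-data bipartition reappears.

## Conventions that drive the numbers

Several published table quantities depend on conventions their sources do
not state. The package fixes them once, documents them here, and keeps
them consistent between the statistics and the tests:

* **Coordinates.** All user-facing coordinates are 1-based closed
  intervals on the forward strand — the native GenBank convention, and the
  one base R and IRanges arithmetic expect. Intervals that span the
  origin of a circular genome have `end < start`.
* **Column classes.** A column is *variable* when at least two distinct
  unambiguous residues occur in it; N never creates variability (a column
  of one residue plus N is not variable). A column is *identical* only
  when every row carries the same unambiguous residue — gaps and N count
  as non-identical, which defines the percent-identical-sites (PID)
  statistic. A column can simultaneously be variable and gap-containing;
  it then counts toward variable sites *and* its gap run contributes to
  indel events. The primary `state` label uses the precedence
  variable > gap_containing > ambiguous > invariant.
* **Indel events.** One event is a maximal run of consecutive columns
  sharing an identical gap pattern (the same nonempty subset of rows
  gapped). Adjacent runs with different patterns are distinct events.
  This makes indel counts well-defined and reproducible; it will count a
  deletion nested inside a longer one as two events, which we accept for
  determinism.
* **Difference-matrix denominator.** Percentages divide by the full
  alignment length by default (`"alignment_length"`), which reproduces
  the scale of published plastome difference tables (181 differences on a
  ~152 kb alignment prints as 0.12%); `"pairwise_ungapped"` is available
  and logged when chosen. Whether the alignment carries one or two IR
  copies is the caller's choice; the pipeline computes the matrix on the
  alignment as supplied and applies IR-deduplication only for tree
  building.
* **Region ranking.** Most divergent first means ascending PID, ties
  broken by more variable sites, then by region name — a total,
  deterministic order.
* **IR deduplication.** Where only one inverted-repeat copy should enter
  a statistic (gene counts, genome-wide trees), the IRa copy — the first
  encountered in genome order — is kept. A gene counts as IR-duplicated
  only when a second full-length copy is annotated.
* **Amplicon lengths are primer-inclusive**: the product runs from the
  first base of the forward primer footprint to the last base of the
  reverse footprint. Published product sizes do not state whether primers
  are included; this choice is recorded so the numbers can be re-examined
  against deposited sequences.

## In-silico PCR

Primer sites are located under IUPAC-aware compatibility: a degenerate
primer code matches any template base in its set, while a template N
matches only a primer N (conservative: an undetermined base should not
create a binding site). Up to `max_mismatches` (default 3) are tolerated
per primer, except in the 3'-terminal `clamp` bases (default 3), which
must be compatible — polymerase extension requires a matched 3' end, so
tolerance there would fabricate products. Both template strands are
searched; circular templates are searched across the origin by doubling,
and coordinates are reduced modulo genome length. The defaults are
tolerant enough for cross-species priming with "universal" primers while
strict where chemistry is strict. Primer sequences ship in a plain-text
table (`inst/extdata/primers.tsv`); two of them (trnHf_05, psbA3_f) are
sourced from the primer literature rather than printed in plastome
comparison papers, are marked as such in the table, and every sequence is
user-overridable.

## Small-scale alignment

Marker-scale sets (each sequence ≤ 10 kb) are aligned by center-star
progressive alignment: the center is the sequence with the largest total
shared k-mer count (k = 6), the others are merged in decreasing k-mer
similarity to the center (ties by input order) via global affine-gap
pairwise alignment (Gotoh, in C++), propagating gaps with "once a gap,
always a gap". Default scores are match +1, mismatch −2, gap open −5,
gap extend −1 (a gap of length g costs `open + g·extend`); traceback ties
prefer substitution over gaps deterministically. At sub-percent divergence
the optimal pairwise alignments are essentially unique, so the star
heuristic is adequate; genome-scale alignment remains an external input
(MAFFT-class tools), not something this package re-implements.

## Neighbor joining, bootstrap, and collapsing

NJ follows Studier–Keppler, with Q-criterion ties broken by the lowest
pair of node indices, so a fixed input yields a bit-identical tree.
Negative branch-length estimates (possible with near-zero distances) are
clamped to 0 with a warning. Bootstrap replicates resample columns with
replacement; because identical columns are interchangeable under iid
resampling, the alignment is first compressed to site patterns and each
replicate draws a multinomial weight vector over patterns, making the
per-replicate cost independent of alignment length (200 replicates on a
9 × 152 kb alignment take about a second). Support values are attached to
the full-data tree as internal node labels; `collapse_low_support()`
contracts internal edges below a threshold into polytomies (children keep
their own branch lengths; the contracted edge's length is dropped).
Collapsing at 0 is the identity and above 100 yields a star tree.
Robinson–Foulds distances compare canonical non-trivial bipartition sets.

A deliberate substitution: published plastome phylogenies are usually
maximum-likelihood trees from RAxML-class engines with model selection.
This package's claim surface is species delimitation and clade recovery
on near-identical genomes, which NJ with column bootstrap resolves; ML
bootstrap percentages from other engines are therefore not comparable
numerically, and only clade membership should be checked against them.

## What the simulator emulates — and what it does not

`simulate_genomes()` generates the data regime the analysis targets:

* nine taxa by default, on a random-topology tree whose join depths are
  evenly spaced over `divergence/2` (default 0.001–0.006 pairwise), so
  realized genome-wide divergences span the configured range and no
  internal branch is vanishingly short;
* ~152 kb circular genomes with LSC (~84 kb), two IRs (25 kb, default)
  and SSC (18 kb); protein-coding, tRNA and rRNA genes, the rRNA operon
  and two further genes duplicated in the IR; intron counts annotated on
  a subset of genes;
* uniform (JC-like) substitutions — at 0.1–0.6% divergence the choice of
  substitution model is immaterial to difference counts — with intergenic
  spacers evolving faster (default multiplier 4, per-spacer overrides for
  planted hotspots); multipliers are normalised to a genome-wide mean of
  1 so the divergence range stays genome-wide;
* geometric-length indels (mean 6 bp, capped at 30) restricted to
  single-copy intergenic spacers, Poisson in number proportional to
  branch length (default 2 per average branch). Keeping the IR indel-free
  lets the simulator maintain IRb as the *exact* reverse complement of
  IRa through evolution, mutations appearing in both copies;
* two planted markers delimited by real universal primer sequences: a
  trnH–psbA-style spacer product of 499 bp at the root (length varies
  with spacer indels, as real products do) and an rbcL-style coding
  product of 599 bp. Primer footprints are masked from substitution and
  indels — "conserved primer-binding sites" are part of the regime, and
  a configuration that could mutate them is rejected.

Because every event is logged in root coordinates, the emitted alignment
is exact (not re-estimated), and the truth difference matrix is computed
from the final aligned rows, so substitution collisions and reversals are
resolved exactly by construction.

The simulator does **not** emulate: sequencing reads, assembly or
annotation errors; heteroplasmy; structural variation (inversions,
IR boundary shifts) — real outgroup comparisons show inversions that this
package's alignment statistics would misinterpret, which is why an
explicit column mask is exposed for externally identified inversion
columns; rate heterogeneity beyond the coding/intergenic split; and
nuclear loci (ITS amplicons must be supplied, not simulated from a
plastome). Passing tests on simulated data therefore demonstrate the
correctness of the bookkeeping and the statistics under the intended
divergence regime, not robustness to assembly artifacts or alignment
error in real data.

## Numerical and degenerate-input choices

* Percentages are rounded half-away-from-zero: difference-matrix percents
  to 2 decimals, PID to 1 decimal, matching the precision of published
  tables; internal computations (NJ distances) use unrounded values.
* Ambiguity codes other than N in input sequences are normalised to N
  with a warning — deposited plastomes are effectively unambiguous, and a
  five-letter internal alphabet keeps every downstream definition simple.
* Inverted-repeat detection requires exact reverse-complement identity
  and at least `min_len` (default 10,000) bp; ties on repeat length break
  toward the smallest start coordinate. Records without such a repeat are
  left unpartitioned with a message, not an error. The search is
  rotation-invariant for circular records (doubled-sequence search with
  coordinates reduced modulo length).
* Alignments with fewer than 4 taxa get trees without support values;
  pipelines with fewer than 3 taxa skip the tree stage with a warning.
* Empty PCR results are empty data frames, not errors; unknown feature
  names raise errors listing near-matches.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data
plus the shipped published difference table. Full-scale checks use the
default 9-taxon, 152 kb configuration with 200 bootstrap replicates;
repeated-seed checks (hotspot ranking across 20 seeds, pipeline runs)
use a reduced 60 kb genome (12 kb IR, 8 kb SSC) that preserves the full
layout — these sizes keep the suite near a minute while exercising every
code path at realistic divergences.

## Known limitations

* The center-star aligner is a heuristic; for divergences far above the
  plastome regime (say >5%) a dedicated MSA tool should be used instead.
* Indel events counted per gap-pattern run slightly overcount nested or
  abutting indels relative to a parsimonious event history.
* NJ bootstrap supports are not comparable to ML rapid-bootstrap values;
  use them for clade presence, not for cross-study numeric comparison.
* `detect_inverted_repeats()` finds exact repeats only; genomes with a
  handful of IRa/IRb differences would report a slightly shorter repeat
  (the longest exact stretch).
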
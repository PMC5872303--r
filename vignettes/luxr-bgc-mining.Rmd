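---
title: "Mining LuxR-linked biosynthetic gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining LuxR-linked biosynthetic gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxrbgc)
```

## The problem

Many bacterial specialized-metabolite pathways are silent in laboratory
culture because the gene clusters that encode them (biosynthetic gene
clusters, BGCs) wait on environmental cues. One well-understood cue is
acyl-homoserine-lactone (AHL) quorum sensing: a LuxR-family transcription
factor, often encoded inside or next to the cluster it controls, activates
the pathway at high cell density. BGCs physically linked to a *luxR*-type
gene are therefore attractive discovery targets — their regulation is
predictable enough to wake them up deliberately, for example by adding AHL.

`luxrbgc` implements the computational side of that idea as a reusable,
tested pipeline:

1. **Mining.** Screen annotated cluster records for genes encoding both
   Pfam domains that define a LuxR-family regulator — PF00196 (DNA-binding)
   and PF03472 (signal-binding) — on the *same* protein, using a HMMER
   `domtblout` hit table. Records whose only biosynthetic-role gene is a
   luxI-type AHL synthase (PF00765) are removed: those clusters were
   predicted as "biosynthetic" solely because of the synthase itself.
2. **Dereplication.** Greedy incremental clustering of the LuxR protein
   sequences at 0.9 identity, keeping one representative cluster per
   identity family.
3. **Classification.** Tabulation of the retained hit list: luxI
   co-occurrence, cluster type, habitat, taxonomic class; per-type
   association frequency (hits / all clusters of that type); and a
   diagnostic-residue subtype call (AHL-binding vs plant-responsive-like vs
   atypical).
4. **GC anomaly.** Sliding-window GC profile of each cluster region and a
   z-test against the genome background, since atypical GC suggests
   horizontal acquisition.
5. **Phylogeny.** Multiple alignment of the representative LuxR proteins
   plus a reference panel, complete gap deletion, p-distance, neighbor
   joining, bootstrap support and outgroup rooting on GerE (a regulator
   with the LuxR DNA-binding domain but no signal-binding domain).

A synthetic-data generator stands in for the cluster database, so every
stage is validated against planted ground truth without any download.

## The screen and its thresholds

A gene qualifies as a LuxR homolog when it has at least one qualifying
`domtblout` hit for PF00196 **and** one for PF03472 on the same protein.
Requiring both domains on one CDS is the stricter of the two possible
readings of "genes encoding both domains"; hits split across two genes in
one cluster do not qualify.

A hit qualifies when its conditional E-value is at most `evalue_max`
(default 1e-5) and it covers at least `coverage_min` (default 0.35) of the
profile model. These two thresholds are **assumptions of this package**:
the original screen did not state its hmmsearch acceptance criteria. They
are exposed in `pipeline_config()`, and every run manifest echoes them
under `assumptions`. The hit set is monotone in `evalue_max` (relaxing the
threshold can only grow it), which the test suite asserts.

The luxI-only filter removes an association exactly when its record's set
of biosynthetic-role genes is non-empty and equals its LuxI gene set. Gene
roles are read from an antiSMASH-style `gene_kind` qualifier and default to
`unknown` when absent; a record with no role annotation is therefore never
removed by this filter.

## Identity, dereplication and the 0.9 cutoff

Pairwise identity is computed from an optimal global alignment
(Needleman–Wunsch with affine gaps, Gotoh recursion; BLOSUM62, gap open 10,
gap extend 0.5) as identical aligned pairs divided by the **shorter**
sequence length. That denominator is the convention of CD-HIT-style
clustering tools; "mutual identity" alone does not pin it down, so the
choice is recorded here. End gaps are penalized and traceback ties are
broken in a fixed order (diagonal, then gap in the second sequence, then
gap in the first), so alignments are deterministic. The scores were
cross-checked against an independent implementation
(`Biostrings::pairwiseAlignment`) and a brute-force recursion in the test
suite.

`greedy_cluster()` mirrors the incremental CD-HIT algorithm: sequences are
sorted by decreasing length (ties lexicographic by id) and each joins the
first existing cluster whose *representative* it matches at or above the
cutoff, else founds a new cluster. No k-mer pre-filter is used — exact
dynamic programming is affordable at hundreds of sequences, and exact
identity is taken as the reference behavior. The representative (longest)
sequence's cluster record is the one retained, a choice the source analysis
left unstated.

## Classification

Association frequency per type is plain arithmetic, `100 × hits / total`,
with zero-total types omitted. Display rounding follows mixed precision:
integers at or above 1%, two decimals below 1% (so 1 in 2,000 prints as
0.05); raw fractions are always retained.

The two diagnostic residues separating AHL-binding from plant-responsive
LuxR proteins are defined as **alignment columns of the reference panel**,
anchored on the plant-responsive references (the first column where every
plant-responsive reference has an M and the AHL consensus differs, then the
first later column with a W likewise), not as absolute residue numbers.
A query is aligned to its nearest reference; a W at the second position
gives `plant_responsive_like`, matching the AHL consensus at both gives
`AHL_type`, anything else is `atypical`. The packaged reference panel
(`inst/extdata/luxr_reference_panel_synthetic.afa`) is a **synthetic
stand-in**, not database sequences: it reproduces the panel's composition
(12 AHL-binding references, 2 plant-responsive references carrying M/W, and
the GerE outgroup) and the diagnostic-residue structure, and is used for
anchoring and for the tree; conclusions about real reference proteins
require a real panel, which `luxr_reference_panel(path = ...)` accepts.

## GC anomaly

Windows are half-open `[i, i + window)` at stride `step` (defaults 500/250
bp — the windowing itself is an artifact choice, since no window size was
published); a trailing remainder longer than half a window is kept. `N`
bases are excluded from both numerator and denominator. A region is
summarized by the maximum, length-weighted mean and minimum window GC.

The anomaly call is a z-test of the region mean against background windows:
`z = (mean_region − mean_genome) / (sd_genome / √n_region_windows)`, with a
two-sided normal p-value and flagging at `p < alpha` (default 0.05). The
original analysis asserted "significantly different" GC without naming a
test; the z-test **is this package's choice** and is labeled as such. The
test assumes independent windows, so the pipeline tests on a
non-overlapping tiling even when the display track overlaps. When only a
genome-wide GC fraction `g` is available (the synthetic records carry one),
a binomial parametric background is used: `mean = g`,
`sd = √(g (1 − g) / window)`. Under the null the type-I error is within
Monte-Carlo error of `alpha`, which the suite verifies over 1,000
simulations.

## Phylogeny

The tree pipeline follows the classical distance workflow: complete
deletion removes every column with a gap or `X` in any row; p-distance is
the proportion of differing positions; neighbor joining uses
`Q(i,j) = (n−2) d(i,j) − R_i − R_j`, joins the arg-min pair (ties broken by
the smallest index pair for determinism), computes limb lengths by the
standard formulas, and clamps negative limbs to zero with the deficit moved
to the sister limb so path lengths are conserved. On any additive matrix
the generating tree is recovered exactly (fuzzed over random 4–12 leaf
trees in the tests, and cross-checked against `ape::nj`). Bootstrap
support resamples columns with replacement, rebuilds the tree per
replicate, and scores each original bipartition; supports are stored in
full and suppressed only at rendering below `support_display_min`
(default 50%). Rooting places the root at the midpoint of the outgroup's
pendant edge.

The built-in `progressive_align()` (k-mer UPGMA guide tree, profile–profile
affine-gap merges scored by mean pairwise BLOSUM62) is a deterministic,
dependency-free default. It does not attempt to reproduce any particular
external aligner; externally computed aligned FASTA is accepted anywhere an
alignment is consumed, which is the recommended route when exact
correspondence with a published alignment matters. Full-scale reference
statistics of the original 152-sequence tree (66 retained positions, total
branch length 29.94) depend on that external alignment and are treated as
context, not targets.

## The synthetic generator

`synth_spec()` encodes the study conditions the pipeline is validated
under:

* **Family structure.** A root LuxR protein (250 aa) spawns `K` family
  founders at identity `1 − (1 − between)/2` to the root; members are
  mutated from their founder at `1 − (1 − within)/2`. Substitution-only
  mutation makes identity exactly controllable (`round((1 − t) L)`
  positions changed), and the triangle bound guarantees every within-family
  pair is at or above `within` (default 0.95) while between-family pairs
  land near `between` (default 0.70) — cleanly straddling the 0.9 cutoff.
  Indel realism is deliberately sacrificed for testability.
* **Screen structure.** Defaults: 3 families of 4/3/2 members, 2 luxI-only
  decoys (whose sole biosynthetic-role gene is a LuxI homolog — the
  exclusion filter's targets), 5 LuxR-negative clusters, and 47% of
  LuxR-positive clusters carrying a LuxI gene. Domain hits are planted as
  hit-table rows (detection is annotation-driven, as in the real
  hmmsearch-based screen), all passing the default thresholds. A minority
  of negative clusters carry a PF00196-only single-domain regulator to
  exercise the dual-domain rule.
* **Composition.** Cluster type (NRPS 26%, PKS 10%, NRPS-PKS 11%, the rest
  spread over bacteriocin/lanthipeptide/thiopeptide/terpene/siderophore/
  beta-lactam/ectoine), habitat (plant-associated 40%, environmental 30%,
  human-associated 20%, other 10%) and taxonomic class (Gamma 41%, Alpha
  31%, Beta 26%, Delta 2%) are allocated by **largest-remainder quota
  within each record stratum** with randomized assignment: the realized
  composition of every dataset — in particular of the LuxR-positive
  population that the downstream tables describe — matches the design
  distribution exactly, rather than only in expectation. The habitat split
  is this package's choice of plausible values respecting the published
  ordering (plant > environmental > human > other); the class and type
  percentages are the published ones.
* **Sequence background.** Regions are i.i.d. nucleotides at `region_gc`
  (default 0.60) against a genome background of `genome_gc` (default
  0.67), a gap wide enough that the GC z-test should flag every region —
  a power fixture. CDS translations are independent of the nucleotide
  sequence (no codon realism), and region coordinates are laid out
  left-to-right with fixed spacers.
* **Determinism.** Global allocations draw from a stream seeded by
  `spec$seed`; each record's content draws from a per-record derived
  stream. Identical spec and seed give byte-identical serialized datasets.

What passing tests on this generator do **not** show: robustness to real
annotation noise (wrong roles, missing translations, fragmented clusters),
to indels and domain rearrangements in LuxR sequences, or to habitat
curation errors — the generator emulates the statistical skeleton of the
screen, not the mess of real records.

## Problem sizes and runtime choices

The validation suites run at deliberately modest sizes chosen to exercise
every code path with comfortable margins: the default 16-record dataset for
mining/dereplication ground truth; 100 fuzzed additive trees of 4–12
leaves for neighbor joining; family recovery at K = 2, 5, 10; 1,000 null
simulations for the GC test's type-I error; bootstrap determinism at tens
of replicates. The paper-shaped acceptance run uses 137 singleton LuxR
families (plus 3 decoys and 10 negatives) so that the dereplicated list has
the published size, and measures composition on it. Full-database counts
(219,499 clusters screened, 2,081 unfiltered hits) depend on a 2015 corpus
snapshot and are treated as reference context throughout.

## Known limitations

* Habitat and taxonomy are consumed as curated metadata, never inferred.
* LuxR regulators acting on distant clusters (violacein-style) are missed
  by design: "associated" means inside the annotated cluster region.
* The GC z-test is a screening statistic, not a horizontal-transfer
  inference; codon-usage or tetranucleotide methods are out of scope.
* The greedy clustering reproduces the incremental algorithm with exact
  identities; heuristic word filters of production tools may split
  borderline clusters differently.
* GenBank parsing targets the antiSMASH-style dialect written by this
  package's own writer plus plain records with `CDS`/`cluster` features;
  EMBL and GFF3 are out of scope.
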
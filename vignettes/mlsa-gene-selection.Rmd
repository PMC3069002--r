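---
title: "Selecting core housekeeping genes for MLSA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting core housekeeping genes for MLSA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsaCore)
```

# The selection problem

Multilocus sequence analysis (MLSA) classifies and identifies bacteria
from the concatenated sequences of a few housekeeping-gene fragments
amplified with broad-range primers. `mlsaCore` operationalises the
selection of those genes from a set of finished genomes as a funnel of
testable criteria. Starting from a catalogue of ubiquitous candidate
genes, a gene survives only if it is long enough to carry signal,
present everywhere, strictly single-copy, not flagged for horizontal
transfer, amplifiable with low-degeneracy primers across the whole
clade, and able to *predict genome relatedness* from its fragment
similarity. This vignette documents the models behind each stage, the
parameters that matter, the numerical choices, and what the simulation
evidence does and does not establish.

# Stage models and parameters

## Screening

* **Length**: a gene passes when the *median* ungapped length across
  taxa is at least `min_len = 900` bp. Shorter genes cannot yield a
  sequenced fragment with enough informative sites; the median resists
  single mis-annotations.
* **Ubiquity**: a sequence must exist for every taxon. A marker missing
  anywhere in the clade cannot anchor a universal scheme.
* **Copy number**: `copy_number()` counts genomic loci reaching 70%
  identity over 70% of the gene, found by exact 12-mer seeding on both
  strands, diagonal clustering of seeds, and verification by global
  (Gotoh, affine-gap) alignment of the spanned segment against the
  gene. The identity/coverage thresholds are configurable; 70/70 is a
  deliberately permissive definition of "close paralogue", because a
  paralogue only needs partial primer homology to corrupt direct
  sequencing.
* **Exclusions**: ribosomal-protein and aminoacyl-tRNA-synthetase genes
  arrive flagged and are dropped; horizontal-transfer evidence is
  treated as curated input (a flag set), never computed, because
  sequence-compositional HGT tests are unreliable at this scale.
* **Linkage**: gene pairs whose genomic gap is below
  `min_separation = 10` kb in a majority of taxa are *reported* as
  linked, not auto-eliminated: linked genes sample correlated histories,
  but which member of a linked pair to keep is a judgement call
  (fragment length, database support), so the report leaves the decision
  to the analyst.

## Variability profiling

Per column, variability is `100 * (1 - n_modal / n_nongap)`, the
fraction of non-gap residues that disagree with the modal residue. This
is the simplest definition that is zero for invariant columns, grows
with disorder, and needs no model of the substitution process. Gaps are
excluded from the denominator; an all-gap column scores 100 because it
offers no primer-binding information. Windows are successive,
non-overlapping 50-column tiles (`step = window = 50`); a trailing
partial window is reported but flagged and excluded from region calling,
since its mean is estimated from fewer columns. Runs of windows strictly
below `conserved_threshold = 15` percent become conserved regions —
empirically the ceiling at which a <= 64-fold degenerate primer can
still be placed — and the complementary runs are hypervariable.

## Primer design and in-silico PCR

Primers are minimal IUPAC consensus sequences of gap-free alignment
slices inside conserved regions, 17–22 nt, with per-primer degeneracy
capped at 64 by default (the product over positions of the IUPAC
set sizes). A valid pair needs at least one hypervariable region
strictly between its two conserved regions — the identification signal —
and a product of 600–900 bp for *every* design taxon, the size range a
capillary sequencer reads directly in both directions with the PCR
primers. Pairs are ranked by total degeneracy, then product size.

In-silico PCR matches primers by IUPAC set membership (a template base
binds if it belongs to the primer code's set). The 3'-terminal 3 bases
must match exactly regardless of the mismatch allowance, reflecting the
requirement of an annealed 3' end for polymerase extension; the default
allowance elsewhere is 0 mismatches, configurable up to 2 for
sensitivity studies. Both template orientations are searched; product
length includes both primers; more than one product flags the pair
non-specific for that template. Note that the published broad-range
Actinobacteridae panel shipped with the package
(`actino_primer_set()`) contains one primer of degeneracy 72, above the
default design cap — the cap is a design-time preference, not a
validity bound, and is not applied to user-supplied primers.

## Genome conserved-region similarity (GCR)

Two genomes are compared through maximal unique matches (MUMs): exact
matches, not extendable in either direction, occurring exactly once in
each sequence. The finder builds a suffix array (prefix doubling,
O(n log² n), robust to repetitive sequence) plus a Kasai LCP table over
the concatenation and extracts MUMs with `min_match = 12`. Both query
orientations are scanned independently. Anchors are chained greedily in
reference order: a match extends the chain when both gaps are at most
`max_gap = 250` bp and the diagonal shift is at most
`diag_factor = 0.15` times the gap; chains carrying fewer than
`min_cluster = 40` matched bases are discarded. Inter-anchor gaps are
closed by global affine-gap alignment (match +1, mismatch −3, gap open
−5, extend −1 — conventional DNA-alignment weights, configurable); a gap
exceeding `2 * breaklen` (breaklen = 500) splits the chain into separate
regions. Region ends are extended outward by ungapped alignment that
keeps the best-scoring prefix within a `breaklen` look-ahead window — a
bounded x-drop rule that stops extension after sustained net-negative
score.

The whole analysis is repeated with reference and query swapped and the
two region sets merged, so regions detectable only from one side are not
lost. When two regions share reference bases, the shared segment is
divided equally at its midpoint; because column-level alignments are not
retained after gap closing, the trimmed regions' identities are
recomputed proportionally (identity is assumed uniform within a region —
adequate because trims are local and regions are long). A region fully
contained in an earlier one is dropped. The summary statistic is

> GCR = Σ (identity_i × length_i) / Σ length_i,

the mean identity of homologous regions weighted by region length, with
coverage fractions of both genomes reported alongside. Identity counts
matched columns over alignment columns, so gaps count against identity.

## The relatedness regression

For each candidate gene, every genome pair contributes a point (SS,
GCR): SS is the fragment percent identity (identical non-gap columns
over columns with at least one residue; both-gap columns skipped,
single-gap columns counted as mismatches), GCR as above, both on the
percent scale. A quadratic `GCR = a·SS² + b·SS + c` is fitted by
ordinary least squares — the quadratic captures the empirically convex
SS–GCR relationship without risking the oscillation of higher orders —
and genes are ranked by R². Genes with R² strictly above
`r2_threshold = 0.85` are selected; their fragments are concatenated
(sequence concatenation, not averaging of per-gene similarities) and the
combined model refitted. Predictions are clamped to [0, 100] and flagged
when the requested SS lies outside the observed range. Collapsing taxa
with 100% identical fragments is available (`dedup_identical`) but off
by default, since deduplication policy belongs to catalogue curation.

## Phylogeny and support comparison

Distances use Kimura's two-parameter correction,
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`, with P and Q the transition and
transversion proportions over comparable columns. Gap handling is
pairwise deletion (columns with a gap or `N` in either member are
skipped) — the common default in distance phylogenetics; complete
deletion can be emulated upstream by masking. Saturation (`1 − 2P − Q <=
0` or `1 − 2Q <= 0`) is an error for a single pair; inside the bootstrap
a saturated replicate is skipped and counted, and more than 10% skipped
replicates aborts the analysis.

Trees are built by Saitou–Nei neighbor joining. Negative branch lengths
— an artefact of noisy distances — are clamped to zero with the deficit
transferred to the sister branch, preserving path lengths through the
parent where possible; on additive matrices NJ is exact and no clamping
occurs. Bootstrap support resamples alignment columns with replacement
from a single seeded generator (`seed` is mandatory; identical seeds
give identical supports), rebuilds the K2P+NJ tree per replicate, and
scores each internal edge of the full-data tree by the percentage of
replicates containing the same bipartition (bipartitions are compared on
canonical taxon sets, so rooting and rotation are irrelevant). Two
marker sets are compared by the fraction of internal nodes with support
strictly above 65%, tested with a Pearson chi-square on the 2×2
above/below table, 1 df, no continuity correction by default (Yates
correction available by flag).

# The synthetic-data generator

`evolve_genomes()` builds a complete, fully known test world:

* an ultrametric tree (balanced or rescaled coalescent; root-to-tip
  height 0.05 substitutions/site by default — a realistic within-clade
  depth at which fragments stay well below saturation),
* a uniform-random ancestral genome (100 kb by default) laid out as
  alternating intergenic blocks and genes,
* K2P site evolution along the tree (transition/transversion rate ratio
  `kappa = 2`) with per-segment rate multipliers: invariant primer
  flanks (rate 0, 50 bp) placed so that products fall inside 600–900 bp,
  hypervariable gene cores (multiplier 6, which at this tree height
  produces window variabilities of 20–30%, comfortably above the 15%
  threshold), and rate-1 backbone,
* per-lineage *accessory* segments, freshly randomised in every tip
  (35% of each intergenic block) — unalignable pan-genome content that
  depresses genome coverage without touching conserved-region identity,
* engineered decoys: a short gene, a gene with a planted ~90%-identical
  paralogue (evolving at rate 1 so tip-to-tip identity stays above the
  70% detection threshold), a gene deleted from one taxon, a flagged
  gene, and a "scrambled" gene whose evolved per-taxon sequences are
  exchanged among taxa by a fixed interleaving permutation — a
  recombination-like history that leaves the variability profile
  marker-like while destroying the fragment's ability to predict genome
  relatedness (observed R² ~ 0.1).

No indels occur inside genes, so gene alignments are exact by
construction and alignment software is not a dependency of the tests.
This is the generator's main idealisation: real fragments contain
occasional indels and alignment error, real genomes rearrange, and real
accessory content is shared patchily rather than unique per lineage.
Passing tests therefore demonstrate the correctness of the algorithms
and the recoverability of planted structure — not robustness to
alignment artefacts, rearrangement, or compositional bias. The
generator also makes no attempt at realistic GC content or codon
structure; variability statistics in real genes are codon-periodic,
which sharpens (not weakens) the conserved/hypervariable contrast the
window profiler needs.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open only inside the compiled
  code; every user-facing coordinate is 1-based inclusive.
* FASTA input rejects IUPAC codes other than `N` unless
  `allow_iupac = TRUE`; ambiguity codes never match exactly in the MUM
  finder and count as mismatches in PCR site scanning.
* `nj_tree` breaks chain-merge ties deterministically (taxon order), so
  trees are reproducible across runs.
* All-gap alignment columns score 100 variability; columns with fewer
  than two residues are errors.
* Degenerate regression designs (fewer than 3 distinct SS values) and
  saturated distance pairs are hard errors rather than silent NAs.
* The equal-split rule for overlapping genome regions degenerates for a
  fully contained duplicate; the later region is dropped.

# Test-scale choices

The unit-test world uses 10 taxa and 50 kb genomes (45 genome pairs),
and the end-to-end acceptance world 10 taxa and 100 kb; both sizes were
chosen so the whole suite completes in minutes while the regression
stage still sees enough pairwise-distance diversity for stable R²
ranking — with 6 taxa (15 pairs) the marker R² estimates straddle the
0.85 threshold and selection becomes a coin flip, which is a property
of small designs, not of the markers. Bootstrap replicate counts are
reduced (20–200) in tests; the package default remains 1000.

# Known limitations

* The genome aligner targets single-contig genomes; multi-FASTA draft
  assemblies must be concatenated or compared contig-wise by the caller.
* Overlap resolution redistributes identity proportionally rather than
  realigning trimmed spans.
* The copy-number search is tuned for desk-scale verification (k = 12
  seeds, 30% diagonal-coverage trigger); highly fragmented or very
  diverged paralogues below ~70% identity are out of its remit by
  design.
* `compare_support` assumes the two trees' node sets are comparable
  samples; it does not pair nodes across trees.
* The scrambled-gene construction exchanges whole gene sequences; it
  does not model partial-gene recombination tracts.
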
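---
title: "celiaclens: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celiaclens: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(celiaclens)
```

# Scope

celiaclens re-implements, as a tested toolkit, the statistics needed to
compare the intestinal mucosa of healthy controls (HC), active celiac
disease (ACD) and treated celiac disease (TCD) across three modalities:
single-cell RNA-seq, TCR repertoires and Visium-style spatial
transcriptomics. Raw read processing, batch integration across
platforms, regulon inference, 2-D embedding aesthetics and histology
image handling are out of scope. Every statistic ships with a synthetic
generator that carries ground truth, so the package's claims about its
own behaviour (calibration, power, recovery) are established on data
whose answer is known — not asserted.

# Data model

Counts are sparse `Matrix::dgCMatrix` objects (genes x units) with
strictly validated invariants (non-negative integers, unique ids).
Annotations, clonotype tables (AIRR-C rearrangement dialect) and
receptor-ligand pair lists are plain data frames; spot lattices are a
light `spatial_dataset` list with 0-based integer coordinates. Two
deliberate data-model choices:

* **Unknown V/J segment names are retained and flagged**, never dropped:
  real repertoires mix IMGT names with platform idiosyncrasies, and a
  reader that silently discards rows biases every downstream fraction.
* **When both nucleotide and amino-acid junctions are present they must
  agree under the standard genetic code**; the repertoire simulator emits
  codon-wise consistent pairs so this invariant is exercised everywhere.

Hex lattices use Visium-style odd-row-shifted indexing: odd array rows
sit half a column to the right, giving interior spots six neighbors.

# Synthetic generators: the stated world

All three generators are pure functions of `(config, seed)`; the defaults
*are* the world the analyses are tested in, chosen once:

**Cells** (`simulate_cells`). Five cell states across 3 HC / 5 ACD /
4 TCD donors (the adult single-cell design), 400 cells per donor, 200
genes. Counts are negative binomial (`mu = base_mean *
2^marker_logfc` on a state's 10-gene marker block, size = 2 shared
across genes — the model gives no gene-specific noise, so the simplest
shared-dispersion NB is used), with a log-normal per-cell depth factor
(sigma 0.3). The default `marker_logfc = 3` (8-fold) represents
major-lineage markers, which are effectively on/off genes; at 4-fold the
embedding itself caps cluster recovery near ARI 0.85 for *any*
clustering method, contradicting the requirement that the default world
be recoverable (ARI >= 0.9), so 8-fold is the calibrated default. The
abundance shift defaults triple the first state's frequency in ACD and
double it in TCD — the persistent disease-associated expansion pattern.

**Repertoires** (`simulate_repertoire`). 8 HC / 7 ACD / 5 TCD donors
(the bulk TCR design), 5000 unique clonotypes each. V segments are drawn
from per-condition usage vectors whose default encodes the headline
effect: the first segment (TRBV28) at 2% of unique clonotypes in HC and
10% in ACD/TCD. J is uniform; the CDR3 is germline prefix `CAS` + random
core (6-12 residues) + suffix `F`, with a codon-wise consistent
nucleotide junction (random synonymous codons, so amino-acid keying
genuinely merges nucleotide synonyms). Clone sizes are zeta-distributed
(exponent 2.5, truncated at 10^4) — a long-tailed expansion law. A
public-pool fraction (default 2%) draws clonotypes from a
condition-shared pool, creating the inter-sample sharing the sharing
statistics measure.

**Spatial** (`simulate_spatial`). A 30 x 30 hex lattice with four
horizontal crypt-villus bands (villus tip, mid villus, crypt, stem
niche) and one circular lymphoid-aggregate focus (radius ~3 spots) near
the crypt band, where aggregates sit in the tissue. Each region has a
composition over six cell types (enterocyte, stem, TRM, Tfh, B, plasma);
expected spot expression is `signatures %*% composition`, scaled to
10,000 counts per spot (a realistic Visium depth), with NB noise (size
10; `Inf` selects the Poisson limit). The default signature matrix has
15 markers per type at 16x background.

What the generators do **not** emulate: gene-gene correlation beyond
type structure, batch and platform effects, doublets, somatic
hypermutation, spot-boundary mixing between adjacent regions, and
realistic transcriptome-wide gene identity. A green test therefore
establishes that a statistic behaves as designed under its own model
assumptions — not that those assumptions hold in any particular tissue.

# Preprocessing

Library-size normalization to `target_sum = 10^4` then `log1p`;
per-gene z-scoring with constants set to 0 and clipping at +-10 (the
conventional defaults; the underlying study's exact thresholds are not
public). HVGs are ranked by variance of log-normalized expression with
deterministic gene-id tie-breaks. PCA feeds a Euclidean KNN graph
(union-symmetrized), clustered by Leiden modularity with an exposed
seed and first-appearance label numbering, so results are reproducible
run to run.

**Signature scoring** subtracts an expression-matched background: genes
are binned into expression deciles (on the pre-scaling means, carried on
the scaled matrix as an attribute) and 50 background genes are sampled
per signature gene from the same bin. This removes the depth/abundance
component that otherwise dominates naive mean-of-z scores.

# Differential abundance

Cluster-level: per-sample fractions within a parent compartment, tested
per cluster by a two-sided Mann-Whitney exact test on the per-sample
fractions (normal approximation with continuity correction when ties
occur, flagged). No cross-cluster correction by default — each cluster
is read as its own panel — with an optional BH flag.

Neighborhood-level: index cells are sampled uniformly without
replacement; each closed KNN neighborhood is scored by

```
lfc = log2((a + p)/(A - a + p)) - log2((b + p)/(B - b + p))
```

with `a`, `b` the neighborhood's condition counts, `A`, `B` the
condition totals and pseudocount `p = 0.5`; significance is the
two-sided (doubling-rule) hypergeometric tail of `a`, BH-corrected
across neighborhoods. This is a deliberately fully-specifiable scheme
with the same readout (per-neighborhood log fold change + FDR dot) as
heavier neighborhood-DA frameworks; the divergence — no negative
binomial GLM over sample replicates, BH instead of graph-aware FDR — is
intentional and means per-donor overdispersion is *not* modeled. TCD is
handled by running ACD-vs-HC and TCD-vs-HC separately.

A scale note: KNN graphs for *clustering* use small k (15), but the
per-neighborhood hypergeometric test needs neighborhoods large enough to
carry signal — with ~25-cell neighborhoods a 3x abundance shift is
undetectable for any method at these totals. DA runs therefore use much
larger k (the acceptance run uses k = 100 on ~4000 cells, neighborhoods
of ~140 cells), mirroring how dedicated DA tools choose k much larger
than clustering defaults.

# Trajectory

The backbone is the Euclidean minimum spanning tree over cluster
centroids; the root cluster is the one with the highest mean root
signature score (API: a per-unit `root_scores` vector from
`score_signature`, or an explicit `root_cluster`). Units project onto
the nearest backbone edge — ties resolved toward the root side — and
pseudotime is the tree distance from the root to the projection.
Terminal edges act as *rays*: projections extend past leaf centroids
(and before a leaf root, with a shift so the earliest unit sits at
tau = 0). Pure segment clamping piles boundary cells into ties at the
extremes and visibly distorts the ordering; extension preserves both
the ordering and tree additivity.

The branch point is the degree->=3 node nearest the root; the trunk is
the root-to-branch-point path, and post-branch units are labeled by the
subtree their projection falls in. Two documented conventions: branch
*proportions* are computed over post-branch-point units only (trunk
cells are in neither branch), and branch *accuracy* on synthetic
truth is measured over truly-branched cells — the fitted branch point
sits at the last trunk centroid, slightly before the true fork, so
trunk cells in between legitimately receive branch labels and would
otherwise be counted as errors of fork localization rather than branch
assignment. Condition densities use a Gaussian kernel with Silverman's
bandwidth on the pooled pseudotime and a shared grid, each curve
renormalized to integrate to 1.

# Repertoire statistics

The clonotype key defaults to (V segment, CDR3 nucleotide); amino-acid
modes are provided because the underlying study does not state its key,
and nucleotide synonyms merge under them.

**Morisita-Horn** is computed over the union of keys exactly as
`2 Σ x_i y_i / [(Σ x_i²/X² + Σ y_i²/Y²) X Y]`; it is symmetric,
scale-invariant and bounded in [0, 1] (property-tested over random
vectors, with the hand-derived 18/19 case frozen as an oracle).
Cluster-level overlap matrices use cluster-aggregated vectors pooled
over samples.

**V-segment usage** is tested per segment by NB regression of
per-sample counts on group with a log offset of the per-sample total.
The dispersion is method-of-moments on Poisson residuals, pooled across
groups and floored at 1e-8; the group coefficient is tested two-sided
by Wald against a *t* reference with residual degrees of freedom — at
5-10 samples per group the normal reference is measurably
anti-conservative (type-I rate ~0.073 vs ~0.05). The "high-frequency"
class marks segments above 1% of pooled *unique clonotypes* (the
study's "total clones" is ambiguous between clones and templates; this
reading is switchable via `count_type`). Calibration (rejection rate in
[0.03, 0.08] under the null across 200 simulated designs) and power
(the injected 2%-to-10% segment reaches q < 0.05 in >= 90% of 50 runs
with the top high-frequency fold change) are acceptance-tested.

**Expansion structure**: quintiles are defined over unique-clonotype
ranks (descending count, ties by first appearance), not cumulative
template frequency; the 2x2 segment-vs-top-quintile table is tested by
Fisher's exact test whose two-sided p (minimum-likelihood rule, 1e-7
relative tie tolerance) is verified against exhaustive hypergeometric
enumeration over *all* tables with margins up to 50. The top-n variant
uses all clonotypes (flagged) when a repertoire is smaller than n.

**CDR3 composition** distinguishes germline-templated positions (first
3 = `CAS`, last 1 = `F`, both configurable) from the non-germline core;
per-residue two-proportion tests compare core usage between groups with
BH. Motif frequencies accept user-supplied regular expressions — the
exact disease motifs live in prior literature, so none are hard-coded.
Sharing reports per-pair shared-key counts, Jaccard and mean shared
CDR3 length, classed within-condition versus between.

# Spatial niches

**Adjacency**: `P[r, s]` is the fraction of ordered neighbor pairs
`(i in r, j in s)` among ordered pairs with `i in r` — row-normalized
per region, self-adjacency kept in the matrix but dropped from the
plotted edge list. The study does not state its normalization; this
convention makes rows sum to 1 exactly and is verified against a fully
enumerated 4x4 half-split lattice (P[left, right] = 1/6).

**Deconvolution** is non-negative least squares (a small Lawson-Hanson
active-set solver; no NNLS package is assumed) of the linear-normalized
spot vector on the signature matrix, columns renormalized to a common
total, weights renormalized to the simplex, residual norm recorded.
Linear (not log) scale matters: it makes a pure-signature spot and a
50/50 column mixture *exactly* recoverable, which the tests exploit.
Deconvolution error grows monotonically as the generator's NB size
parameter falls — also acceptance-tested.

**Colocalization** is pairwise Spearman correlation of deconvolved
proportions across spots (edge threshold 0.3 by default); constant
columns give NA rather than a spurious edge. Region markers use
rank-sum region-vs-rest tests with a log2 fold change of linear means
(pseudocount 0.1). Region gene-set enrichment scores the mean scaled
expression of the set over a region's spots against `n_perm`
expression-decile-matched random sets; `p = (1 + #null >= obs)/(1 +
n_perm)` never reaches 0, and BH runs across regions.

# Receptor-ligand and susceptibility gene sets

Cell-type pair scores are `mean(ligand in sender) x mean(receptor in
receiver)` on log-normalized data, with a null from shuffling cell-type
labels (999 permutations by default, seeded), BH within pair across
type combinations. Region pair scores default to the `min` of the two
partners' mean scaled expressions — a pair scores highly only where
*both* partners are expressed, the coexpression reading of the bubble
display; the `product` scheme is provided since the display's exact
statistic is not recoverable. Detection is `count > 0` (configurable).
Cell-type gene-set scores reuse the expression-matched permutation
machinery of the spatial module.

# Determinism and the CLI

Every stochastic step takes an explicit seed; generators are pure in
`(config, seed)`; Leiden runs under a set seed with first-appearance
relabeling; permutation nulls are seeded. The CLI (`run_cli()`, wrapper
script in `inst/cli/`) writes TSV/JSON through a single deterministic
writer and logs the resolved configuration including the seed next to
each stage's outputs, so a rerun with the same config and seed is
byte-identical — which the acceptance suite checks literally, byte by
byte, across all sixteen subcommands. Configuration files are JSON
(nested key/value) read by jsonlite.

# Known limitations

* The neighborhood DA test treats cells as exchangeable within
  condition; per-donor overdispersion is not modeled, so its p-values
  are calibrated under the simulator's world, not under strong donor
  effects.
* The MoM-dispersion NB Wald-t test is a small-sample approximation;
  with fewer than ~3 samples per group it degrades to a Poisson test.
* The centroid-MST pseudotime places the branch point at a centroid,
  before the geometric fork; fork localization is only as fine as the
  cluster granularity.
* NNLS deconvolution assumes the signature matrix spans the spot
  transcriptome; missing types are absorbed into the closest available
  signature.
* No batch correction: multi-platform integration is explicitly out of
  scope, and cross-platform inputs should be analyzed separately.
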
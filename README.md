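# celiaclens

Statistics for dissecting the celiac disease lesion from single-cell
transcriptomics, T cell receptor (TCR) repertoires and Visium-style
spatial transcriptomics — built for studies that compare healthy controls
(`HC`), active celiac disease (`ACD`) and treated celiac disease (`TCD`)
across duodenal biopsies.

Who it is for: computational biologists who have cell-level count
matrices, AIRR rearrangement tables and spot-lattice counts and want the
*bespoke* statistics of a celiac multi-omics study as reusable, tested
functions rather than one-off notebook code.

## What it computes

| Analysis | Functions | Core statistic |
|---|---|---|
| Neighborhood differential abundance | `build_knn`, `neighborhood_enrichment` | per-neighborhood `lfc = log2[(a+p)/(A-a+p)] - log2[(b+p)/(B-b+p)]` with a two-sided hypergeometric tail p and BH FDR |
| Cluster proportions | `cluster_proportions`, `test_proportions` | exact two-sided Mann-Whitney on per-sample fractions |
| Pseudotime and branches | `fit_pseudotime`, `assign_branches`, `condition_density`, `branch_proportions` | centroid minimum-spanning-tree backbone; tau = tree distance from root; branch point = first degree-3 node |
| Repertoire overlap | `aggregate_clonotypes`, `morisita_horn` | `MH = 2 Σ x_i y_i / [(Σx_i²/X² + Σy_i²/Y²) X Y]` |
| V-segment usage | `v_usage_test` | NB regression of per-sample segment counts with log-total offset, method-of-moments dispersion, Wald-t p, BH |
| Expansion structure | `unique_v_fraction`, `top_expanded_v_fraction`, `quintile_enrichment` | rank quintiles of unique clonotypes; Fisher exact 2x2 |
| CDR3 composition | `cdr3_aa_usage`, `motif_frequency`, `clonotype_sharing` | germline-masked residue frequencies, motif rates, pairwise Jaccard |
| Spatial regions | `cluster_spots`, `region_adjacency`, `region_proportions`, `region_markers` | row-stochastic neighbor-pair fraction matrix `P[r,s]` over the hex/square lattice |
| Deconvolution | `build_signatures`, `deconvolve`, `colocalization` | non-negative least squares of normalized spot profiles on type signatures; Spearman colocalization |
| Receptor-ligand + gene sets | `score_celltype_pairs`, `score_region_pairs`, `region_set_enrichment`, `celltype_set_score` | permutation p = (1 + #null ≥ obs)/(1 + n_perm) with label shuffles or expression-matched gene sets |

Synthetic generators with ground truth (`simulate_cells`,
`simulate_repertoire`, `simulate_spatial`) emulate the statistical
structure the analyses assume — multi-donor condition designs, a
disease-skewed V segment (2% of unique clonotypes in controls vs 10% in
disease), long-tailed clonal expansion, and a banded crypt-villus lattice
with a focal lymphoid aggregate — so calibration, power and recovery are
all testable without patient data.

## Worked example

Simulate bulk-TCR-style repertoires for 8 HC / 7 ACD / 5 TCD donors
(5000 unique clonotypes each, the default design) and test V-segment
usage skewing:

```r
library(celiaclens)

sim <- simulate_repertoire(repertoire_sim_config(seed = 42))
vu  <- v_usage_test(sim$table, groups = c("ACD", "HC"))
head(vu[order(vu$q), c("segment", "lfc", "p", "q", "freq_class")], 3)
#>   segment        lfc            p            q freq_class
#> 6  TRBV28  2.3804997 9.650464e-15 1.158056e-13       high
#> 9 TRBV5-1 -0.1885102 5.201208e-06 3.120725e-05       high
#> 2  TRBV15 -0.1169238 1.654083e-04 6.616333e-04       high

fr <- unique_v_fraction(sim$table, "TRBV28")
round(tapply(fr, sub("_r[0-9]+$", "", names(fr)), mean), 3)
#>   ACD    HC   TCD
#> 0.101 0.019 0.103
```

The disease-associated segment comes out on top with a ~2.4 log2
fold-change and survives BH correction; mean per-donor usage reproduces
the generator's stated world (about 10% of unique clonotypes in ACD and
TCD versus 2% in controls). `lfc` is the NB-model group effect in log2
units, `q` the BH-adjusted Wald p, and `freq_class` marks segments
carrying more than 1% of pooled clonotypes.

Abundance-weighted repertoire overlap between two donors:

```r
vecs <- aggregate_clonotypes(sim$table)        # (V, CDR3-nt) keys
morisita_horn(vecs$ACD_r1, vecs$ACD_r2)
#> [1] 0
```

Mostly-private repertoires give a Morisita-Horn index near 0; identical
repertoires give exactly 1.

## Command line

Every stage is also a CLI subcommand (installed at
`inst/cli/celiaclens`, or call `celiaclens::run_cli()` directly):

```sh
celiaclens simulate cells --config cells.json --seed 9 --out sim/
celiaclens preprocess --counts-dir sim/ --out prep/
celiaclens da neighborhoods --annotation sim/annotation.tsv \
    --embedding prep/embedding.tsv --out da/
celiaclens repertoire vusage --airr rep/airr.tsv --out vu/
celiaclens spatial regions --spatial-dir sp/ --out regions/
```

All outputs are TSV/JSON; each stage logs its resolved configuration and
seed, and reruns with the same config and seed are byte-identical.

## Documentation

The methods vignette (`vignettes/celiaclens-methods.Rmd`) describes each
model, its assumptions, the tunable parameters, what the generators do
and do not emulate, and the numerical choices made where the underlying
study left the method open.
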
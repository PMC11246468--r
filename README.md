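# lungdyn

Temporal, trajectory, spatial and signaling dynamics of a developmental
single-cell atlas — the quantitative toolkit of a human fetal lung atlas
study (gestational weeks 10–19), implemented as a tested, reusable R
package and exercised end to end on a seeded synthetic atlas with full
ground truth.

## What it does

* **Composition over gestational week.** Per-type cell counts are modeled
  as binomial with a logit link and constant / linear / quadratic
  dependence on gestational week, zero-centered normal priors (sd 2.5) on
  standardized coefficients, MAP fits with Laplace 95% bands, and family
  selection by exact leave-one-out cross-validation
  (`fit_composition()`, `select_model()`).
* **Trajectories.** Cluster-backbone pseudotime from an MST over cluster
  centroids in 30-PC space (`infer_backbone()`); lineage-associated genes
  by spline regression on pseudotime at FDR < 0.01 per lineage
  (`association_test()`); gene modules by Ward linkage on 1 − correlation
  (`gene_modules()`); vignette-split cluster-graph connectivity
  (`vignette_connectivity()`); fate probabilities from an absorbing Markov
  chain with a pseudotime-directed kernel (`fate_probabilities()`).
* **Spatial statistics.** Co-occurrence profiles around a focal type,
  permutation neighborhood enrichment at radius 75, deconvolution-weight
  colocalization, and the "spatially close types" rule used to restrict
  ligand senders (`cooccurrence_profile()`, `neighborhood_enrichment()`,
  `weight_colocalization()`, `proximal_types()`).
* **Signaling.** Mass-action Hill ligand–receptor probabilities with
  cell-label permutation significance (p < 0.01), early/mid/late vignette
  contrasts with an exact sample-level permutation null, and pathway
  information flow with exact paired signed-rank tests
  (`permutation_significance()`, `temporal_compare()`,
  `information_flow()`).
* **Benchmarking.** Projection of an hPSC/organoid-style query into the
  reference PCA space, joint clustering with a strict >100-query-cell
  filter, ordering of retained clusters by average reference pseudotime,
  marker scores normalized so the own-type median is 1, and Spearman
  staging on top-50 per-week genes (`project_query()`, `joint_clusters()`,
  `position_clusters()`, `benchmark_report()`, `score_cells()`,
  `stage_correlation()`).
* **Markers.** One-vs-rest Wilcoxon rank-sum markers (logFC > 0.25,
  positive only, BH within cluster) and the overlap coefficient
  |A∩B| / min(|A|, |B|) (`rank_markers()`, `overlap_coefficient()`).
* **Synthetic atlas.** `sim_config()` / `make_atlas()` / `make_spatial()`
  generate seeded data with planted markers, composition trends,
  a branching trajectory, maturation programs, spatial niches and
  vignette-restricted ligand–receptor switches — with the ground truth
  returned alongside the counts.

## A worked example

```r
library(lungdyn)

cfg   <- sim_config(seed = 7)            # 19 samples, GW 10-19
atlas <- make_spatial(make_atlas(cfg))
qc    <- qc_filter(atlas$counts, min_features = 50)
expr  <- transform_expr(qc)              # normalize, HVGs, 30 PCs

# composition trend of type D (planted quadratic)
meta <- qc$cell_meta
d    <- composition_data(
  tapply(meta$gestational_week, meta$sample_id, unique),
  tapply(meta$true_type == "D", meta$sample_id, sum),
  tapply(meta$true_type,        meta$sample_id, length))
select_model(d)
#> composition_select: best family = quadratic
#>   LOO scores: constant=-150.155, linear=-149.972, quadratic=-60.187

# trajectory: root A, branches C and D
model <- infer_backbone(expr$embedding, meta$true_type, "A")
model
#> trajectory_model: root A -> C, D ( 5700 cells )
#>   lineage C : A -> B -> C
#>   lineage D : A -> B -> D
cor(model$pseudotime, atlas$truth_pseudotime[meta$cell_id],
    method = "spearman")
#> [1] 0.9651
```

The selected quadratic family matches the planted trend for type D, the
backbone recovers the planted Y topology A→B→{C,D}, and the inferred
pseudotime rank-correlates with the latent truth at 0.96.

A complete run over every stage — QC, clustering with the resolution
stability diagnostic, markers and scores, composition, trajectory,
spatial, signaling, and benchmarking of a held-out synthetic query — is

```r
res <- run_pipeline(demo_config(out_dir = "demo_run", seed = 1))
```

which writes CSV artifacts and a `manifest.json` of all parameters and
seeds; rerunning the same configuration reproduces the outputs byte for
byte.

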
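---
title: "Models and methods behind lungdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lungdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

lungdyn implements the quantitative core of a developmental single-cell
atlas study of the human fetal lung: how cell-type composition changes with
gestational week (GW), how cells order along differentiation trajectories,
how cell types organize in space, how ligand–receptor signaling is rewired
between developmental windows, and how an hPSC-derived (organoid) dataset
can be benchmarked against the primary atlas. Everything is exercised on a
seeded synthetic atlas with full ground truth, so each statistical claim in
the package is backed by a recovery or calibration test.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where the underlying procedures
left genuine freedom.

## The synthetic atlas generator

`sim_config()` / `make_atlas()` define a generative model with the
statistical structure the downstream analyses assume:

* **Samples.** By default 19 tissue samples, one gestational week each
  (weeks 10–19 cycled), mirroring the design size of a fetal-lung atlas.
  Week is a sample-level covariate: all cells of a sample share one GW.
* **Composition.** Each cell type has a logit-scale polynomial in centered
  GW — constant, linear, or quadratic. Expected per-sample proportions are
  the inverse-logit values renormalized across types; observed type counts
  are multinomial.
* **Counts.** Negative binomial with gene-specific baseline means
  (log-normal across genes), per-sample and per-cell depth factors
  (log-normal, sd 0.2 and 0.1), and a common size (inverse-dispersion)
  parameter (default 10). NB matches the overdispersion of UMI counts;
  ambient RNA, doublets and batch structure beyond depth are deliberately
  out of scope.
* **Markers.** Disjoint blocks of `markers_per_type` genes get a
  `marker_effect` log-scale shift in their own type. Marker baselines are
  set high enough (`base_signal = 2`) that markers are well-expressed
  genes rather than dropout-dominated ones.
* **Trajectory.** Cells of the types on the configured root→leaf paths
  carry a latent pseudotime in [0, 1] (uniform within their type's path
  segment) and a branch label. Trajectory genes follow logistic activation
  profiles: *trunk* programs activate before the bifurcation and are shared
  by all branches; *branch* programs activate after it and are frozen at
  the bifurcation value for cells on the other branch. This trunk/branch
  split is what makes sibling branches diverge from each other more than
  from their parent — without it, a centroid tree over the types
  degenerates into a chain.
* **Maturation.** A set of genes with logistic activation windows in GW
  (centers staggered over the week range and slightly beyond it, shared by
  all cell types). These are the genes that make developmental stages
  transcriptionally distinguishable, which per-week staging requires.
* **Signaling.** Planted ligand–receptor pairs: the ligand is boosted in
  its sender type only during its active vignette (early GW10–13, mid
  GW14–16, late GW18–19); receptor subunits are elevated in the receiver
  throughout. Ligands are switch-like (low baseline), so the planted boost
  moves the interaction probability substantially instead of saturating.
* **Space.** Cells are placed uniformly within configured niche discs on a
  [0, 1000]² domain (so a 75-unit neighborhood radius is meaningful at
  default density), with types drawn from per-niche mixtures; pseudo-spot
  weights are local type proportions on a regular grid.

Gene-program parameters (baselines, activation windows, directions) are
drawn under a separate `program_seed`, while `seed` drives the sampling
noise. Two atlases that share a configuration but differ in `seed` are
therefore biological replicates of the *same* tissue — the property that
makes query-versus-reference benchmarking meaningful.

What passing tests on this generator do **not** show: robustness to batch
effects, ambient contamination, doublets, unbalanced designs, or
annotation error in real atlases.

## Preprocessing

`qc_filter()` applies the atlas QC rule: cells with fewer than 200
detected features or more than 15% mitochondrial counts are removed, then
genes detected in fewer than 3 of the surviving cells. Cell filters come
first and the pass is applied once, so the operation is idempotent; the
mitochondrial fraction uses raw counts.

`transform_expr()` normalizes each cell to a common library target
(default: median library size), takes log(1 + x), ranks genes by
variance/mean dispersion z-scored within up to 20 equal-frequency
mean-expression bins, and runs PCA on the z-scaled (clipped at ±10) top
3000 HVGs, keeping 30 components. The per-gene centering/scaling and
loadings are kept so an external query can be projected into the same
space.

`cluster_graph()` builds a shared-nearest-neighbor graph (Jaccard overlap
of kNN sets including self, pruned below 1/15) and optimizes Louvain
modularity at the requested resolution; given a seed the partition is
deterministic. `resolution_stability()` is the cluster-tree diagnostic:
for consecutive resolutions, each child cluster's *in-proportion* from
each parent is the fraction of its cells contributed by that parent; a
resolution is flagged over-clustered when a child draws at least the
threshold (default 0.1, the conventional notion of a real tree edge) from
two or more parents, and the largest unflagged resolution is recommended.

## Markers, scores, staging

`rank_markers()` is a one-vs-rest two-sided Wilcoxon rank-sum per gene per
cluster. The exact null distribution is used when both groups have at most
50 observations and there are no ties; otherwise the normal approximation
with tie and continuity correction. The log fold change is
`ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`; rows with
`log_fc <= 0.25` (or non-positive change) are dropped *before*
Benjamini–Hochberg adjustment, which is applied within each cluster.

`score_cells()` scores a gene set as the mean expression of the set minus
the mean over controls sampled from expression-matched bins (25 bins, 50
controls per set gene, seeded) of the background pool — all genes
expressed in strictly more than 10 cells, excluding the set. With
normalization, each type's column is divided by the median score of its
own cells, pinning the own-type median at exactly 1.

`stage_correlation()` stages a query against per-week reference profiles
with Spearman correlation over the union of top-50 stage-vs-rest marker
genes; ties in the best stage break toward the lower week. Profiles are
group means rather than per-cell values. Single-sample-per-week references
carry composition noise comparable to adjacent-week differences, so the
benchmark analyses use two samples per week for the reference.

## Composition trends over gestational week

For each cell type, per-sample counts (out of the sample's total cells)
follow a binomial GLM with a logit link and a constant, linear, or
quadratic dependence on GW. The covariate is centered and scaled to unit
SD; every coefficient gets a zero-centered normal prior with sd 2.5. The
fit is the posterior mode (a convex Newton optimization; the prior removes
separation failures at all-zero counts), and 95% bands come from the
Laplace approximation propagated through the inverse logit. This
MAP-plus-Laplace scheme is a deterministic substitute for MCMC at this
design size (a Gauss–Hermite posterior-predictive variant was
indistinguishable at these binomial totals).

`select_model()` scores each family by exact leave-one-out: every sample
is held out, the model refit, and the held-out binomial log density
accumulated pointwise. Families are compared from simple to complex and a
more complex family is preferred only when its LOO advantage exceeds one
standard error of the pointwise difference (`se_margin = 1`) — the usual
reading of a LOO comparison table, under which near-ties resolve toward
the simpler trend. With a plain argmax, a quadratic overfits a true
constant in roughly a fifth of replicates; with the SE margin that rate
drops below 5% while strong planted trends are still selected in well
over 90% of replicates.

## Trajectories

`infer_backbone()` builds a minimum spanning tree over cluster centroids
in PC space and treats every root-to-leaf path as a lineage. A cell's
pseudotime is the arc length of its orthogonal projection onto the
piecewise-linear backbone of its nearest lineage; lineage weights are
normalized inverse distances. This replaces smooth principal curves with a
simpler deterministic construction; projections clamp at backbone ends, so
pseudotime is exact between end centroids and saturates beyond them.

`association_test()` regresses each gene on a natural cubic spline basis
of pseudotime (df = 10, knots at quantiles) against an intercept-only
model with an F-test, per lineage; cells count toward every lineage whose
weight is at least uniform (so trunk cells inform both branches). BH
adjustment and the 0.01 FDR threshold are applied within each lineage
separately. `gene_modules()` clusters lineage genes by Ward linkage on
1 − Pearson correlation and smooths heatmap rows with the same spline
basis.

`vignette_connectivity()` splits cells into early/mid/late bins (late
starting at GW17 by default here; the signaling convention starts at 18 —
the discrepancy between the two conventions is inherited from the source
analyses and both are exposed as parameters), builds a kNN graph per bin,
and scores cluster pairs by observed/expected inter-cluster edges capped
at 1, oriented from lower to higher mean pseudotime.

`fate_probabilities()` forms an absorbing Markov chain on the kNN graph:
edge weights are logistic in the pseudotime difference (scale defaulting
to the SD of differences over edges), rows renormalize, terminal-cluster
cells absorb, and absorption probabilities are solved exactly as a sparse
linear system. Rows sum to 1 by construction and the result matches a
dense solve to near machine precision.

## Spatial statistics

`cooccurrence_profile()` pools, for each radius, every non-focal cell
within that distance of *any* focal cell (closed ball) and reports type
proportions of the pool; an empty pool is reported missing, not zero.
Pooling over focal cells (rather than per-cell averaging) is one of two
defensible readings of the co-occurrence proportion; it is the
implemented one.

`neighborhood_enrichment()` counts radius-graph edges (default 75 units)
between each pair of types and standardizes the observed count against
seeded label permutations. `weight_colocalization()` correlates
deconvolution-weight columns across spots and orders types by
average-linkage clustering on 1 − correlation. `proximal_types()` turns
either statistic into the "spatially close" sender set for signaling; the
default criterion is enrichment z > 0, made explicit because no numeric
rule is stated in the source analyses.

## Ligand–receptor signaling

`interaction_probability()` uses a minimal mass-action Hill form: L and R
are 25%-trimmed means of ligand and receptor expression in sender and
receiver (geometric mean across subunits), and the probability is
`L·R / (0.5 + L·R)`. This is a deliberate simplification of full
communication models (no cofactors or antagonists); the permutation
machinery around it is the point.

`permutation_significance()` permutes cell-type labels (at least 19
permutations; p = (1 + #{null ≥ obs}) / (1 + n)) and flags interactions
at p < 0.01 within each vignette.

`temporal_compare()` contrasts early against the best of mid/late per
(sender, receiver, pair). Because gestational week is a **sample-level**
covariate, the null permutes the vignette assignment of whole samples —
permuting cells would split samples across vignettes and understate
between-sample variability, which we found produces spurious calls. When
the number of distinct sample-to-vignette assignments is enumerable
(≤ 20 000) the null is exact and deterministic, with trimmed means cached
per sample subset; otherwise seeded random sample permutations are used.
A call additionally requires the probability contrast to exceed
`min_delta` (default 0.3): permutation rank extremity alone fires at rate
α even for flat pairs, and sample-level depth variability moves null
contrasts by up to ~0.2 at the default design size, while planted
switches move them by 0.6–0.8. The gate plays the same role as a
fold-change threshold next to a DE p-value, and its default was
calibrated on the generator's null (decoy-pair) contrast distribution.
Sender sets can be restricted to spatially close types per receiver.

`information_flow()` sums significant interaction probabilities per
pathway per vignette and compares vignettes with a paired Wilcoxon
signed-rank test across pathways. The exact distribution is computed by
dynamic programming over doubled midranks (n ≤ 25), which remains exact
under tied differences — a uniform +1 shift over 8 pathways yields
exactly p = 2/256.

## Benchmarking an organoid-style query

`project_query()` normalizes the query with the reference parameters and
projects it onto the reference loadings (genes matched by identifier;
reference HVGs missing from the query are tolerated up to 50%). This
deterministic reference-projection replaces graph-based batch integration;
it is sufficient for the positioning contract and exactly reproduces
reference coordinates for a copied query. `joint_clusters()` clusters the
stacked embedding (the source analyses use resolution 2.25) and retains
clusters with strictly more than 100 query cells. `position_clusters()`
assigns each retained cluster the mean reference pseudotime of its
reference cells and orders clusters by it (clusters without reference
cells are excluded with a warning — the behaviour in that unstated corner
is this package's choice). `benchmark_report()` joins positions,
normalized score medians, and Spearman staging into one table.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains every stage on a synthetic atlas and writes CSV
artifacts plus a JSON manifest of all parameters and seeds; identical
configurations produce byte-identical outputs. The bundled
`demo_config()` reduces scale-dependent values (250 cells per sample, a
400-gene panel, 50-feature QC floor, joint resolution 0.5 with a 30-cell
retention floor) while keeping every study threshold that is not
scale-bound at its default.

The test-suite problem sizes are chosen to make each statistical property
measurable in minutes on one CPU: composition recovery uses 19 samples of
5000 cells over 100 replicates; lineage-gene calibration uses 1000 null
genes and 50 planted genes across 3 seeds; the enrichment null uses 3000
cells and 20 types over 1000 permutations across 3 seeds; staging and
ordering use 20 seeded query runs against a 20-sample reference.

## Known limitations

* Piecewise-linear backbones flatten pseudotime beyond the terminal
  centroids and assume the MST over centroids reflects the true topology.
* The composition model treats types marginally; no joint multinomial
  model, so renormalization-induced dependence between types is ignored.
* The Hill signaling model omits cofactors; probabilities are comparable
  within this package, not with full communication frameworks.
* The sample-level temporal null requires enough samples per vignette to
  have power; with very few samples the exact null is valid but
  conservative.
* The generator does not simulate batch effects, ambient RNA, or
  doublets; results on real atlases depend on upstream handling of those.
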
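---
title: "Assessing single-cell cluster robustness with the Cell Stability Score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing single-cell cluster robustness with the Cell Stability Score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clustering is the central inferential step of most single-cell RNA-seq
analyses: cells are grouped into putative subpopulations, and everything
downstream (marker genes, annotations, comparisons between conditions)
inherits those group boundaries. Yet clustering algorithms will happily
partition noise, and a partition of a *sample* of cells need not survive a
different sample. `cellstab` quantifies that fragility at the resolution
where it matters — per cell — instead of only reporting one number per
clustering.

## The Cell Stability Score

Fix a *reference* partition: the clustering of the full count matrix with
the master seed. Then perturb: for run $b = 1, \dots, B$ remove a uniformly
random fraction $f$ of cells and re-cluster the retained submatrix with the
same engine. For a cell $i$ retained in run $b$, let

* $A_{i,b}$ = the cells sharing $i$'s **reference** cluster, restricted to
  the cells retained in run $b$ (this set contains $i$), and
* $B_{i,b}$ = the cluster of run $b$ that contains $i$.

The run's agreement for cell $i$ is the Jaccard index
$J(i,b) = |A_{i,b} \cap B_{i,b}| \,/\, |A_{i,b} \cup B_{i,b}|$, and the Cell
Stability Score is the mean over the runs retaining $i$:

$$\mathrm{CSS}(i) = \frac{1}{|R_i|} \sum_{b \in R_i} J(i,b), \qquad
R_i = \{ b : i \text{ retained in run } b \}.$$

Because both sets contain $i$, a defined CSS is always in $(0, 1]$; it is 1
exactly when $i$'s reference co-cluster set (restricted to retained cells)
is reproduced verbatim, and it depends only on co-membership, never on
label values. Cells never retained — probability $f^B$, negligible at the
defaults — are reported as missing rather than zero.

Two design choices here were genuinely open and are fixed as follows:

* **Mean vs. thresholded aggregation.** CSS averages $J(i,b)$ over runs.
  A variant that reports the *fraction* of runs with $J(i,b)$ above a
  cutoff is available via the `threshold` argument of
  `cell_stability_score()`; the mean is the primary definition because it
  preserves gradations among unstable cells.
* **The reference anchor.** Persistence needs a fixed anchor partition; we
  use the single full-data clustering under the master seed rather than an
  average of several references, keeping the score interpretable as
  "persistence of *this* clustering".

Alongside CSS, `cluster_stability()` reports the clusterwise
bootstrap-stability of Hennig: per reference cluster and run, the maximum
Jaccard overlap with any run cluster, averaged over runs — one number per
cluster rather than per cell. `silhouette_scores()` supplies the standard
silhouette comparison.

## Perturbation scheme and defaults

* `f = 0.1`: each run removes 10% of cells. Large enough to probe sampling
  fragility, small enough that cluster sizes are essentially preserved.
* `B = 160` for a single stability analysis, and at least 100 permutations
  are recommended for a settled CSS estimate; the sweep default is
  `B = 100`.
* Run $b$'s randomness (both the removed subset and the clusterer seed)
  derives solely from `master_seed + b`, so runs are independent,
  order-free and reproducible; a re-run with the same master seed is
  bit-identical.

## Choosing k: the CSS sweep

`css_sweep()` repeats the full analysis for each candidate `k`, reusing the
same master seed — hence the same removal subsets — across candidates, a
paired design. `best_k` maximizes mean CSS (ties to the smaller `k`).
Under-clustering merges genuinely distinct groups whose members then
oscillate between partitions; over-clustering splits homogeneous groups
along noise directions that reshuffle under perturbation; both depress mean
CSS, which peaks at the planted `k` in the synthetic presets. Silhouette
summaries are tabulated alongside for comparison but do not enter the
`best_k` decision.

## Clustering engines

The stability machinery is engine-agnostic: anything honoring the
`Partition` contract can be scored. Two engines are built in:

* `kmeans_log` — k-means with k-means++ seeding, 10 restarts, best inertia
  (ties to the lowest restart index), on the top `n_pcs = 10` principal
  components of `log10(count + 1)`-transformed counts. This mirrors the
  input conventions of k-means-style single-cell tools that take `k` as
  input.
* `graph_community` — a symmetrized, unweighted kNN graph
  (`n_neighbors = 15`, Euclidean in the same PCA space) with Louvain
  modularity communities, mirroring graph-based engines where `k` emerges
  from the data; `propose_k()` exposes the community count directly.

Both engines cluster PCA scores rather than the full gene space because
full-dimensional distances are noise-dominated; `n_pcs` is configurable.
The PCA uses the cells-by-cells Gram-matrix eigendecomposition (exact, and
fast when genes far outnumber cells) with a deterministic sign convention.
A matrix in which all cells are identical yields a single-cluster partition
with a warning instead of an error, so a perturbation schedule never aborts
mid-run. External engines plug in as callbacks returning one label per
cell. Note that modularity optimization on a homogeneous point cloud can
still report several communities — `propose_k()` is a proposal to feed into
a sweep, not an unbiased estimator of "1" on structureless data.

Silhouettes are computed in the clusterer's transformed/PCA space, making
them comparable across `k`; singleton clusters and all-identical
configurations score 0 by convention.

## Quality control

`genes_umi()` counts, per cell, the genes supported by at least
`min_units` counts (default 3 for UMI data; 5 is the usual choice for
read-level data) and the total UMI. `mito_ribo_umi()` reports the
percentage of mitochondrial and of ribosomal genes **among detected
genes** — a gene-count fraction, not a UMI fraction (a UMI-weighted variant
is available behind `umi_based = TRUE`). Cells detecting nothing get `NA`
rather than a division by zero. Flags come from symbol conventions: `MT-`/
`mt-` prefixes for mitochondrial genes, `Rps*`/`Rpl*` families for
ribosomal; mitochondrial ribosomal proteins (`Mrp*`) are excluded unless
`include_mrp = TRUE`, since the cytosolic families are what QC filtering
conventionally targets.

`filter_cells()` applies the standard defaults — at least 100 detected
genes and at least 100 total UMI — evaluating every rule on the full
matrix, removing cells failing any rule, and only then (optionally)
dropping flagged mito/ribo gene rows. Every removal is recorded in an
audit trail in application order.

`lorenz_filter()` targets cells whose counts are concentrated on very few
genes: each cell is scored by the Gini coefficient of its gene-count
vector (the summary statistic of its Lorenz curve), and one-sided robust
z-scores (median/MAD) with normal tail p-values and BH adjustment call the
outliers. This is a reconstruction of the
estimate-background-then-discard idea behind Lorenz-statistic cell
filtering, built to be testable; it is documented as such and makes no
claim of numerical agreement with any external implementation. When the
MAD degenerates to zero, cells above the median score are treated as
infinitely extreme and all others as unremarkable, which preserves the
"identical cells are never outliers" property.

`count_depth_fit()` is a diagnostic for sample-specific count-depth
dependence: per gene (non-zero in at least 10 cells), a median (tau = 0.5)
quantile regression of `log(count + 1)` on `log(total UMI)` over the cells
expressing the gene, with genes aggregated into equal-frequency slope
groups. The conditional-on-expression fit and the `+1` offset are our
resolutions of details the quantile-regression contract leaves open; the
L1 line fit is an IRLS implementation tested against a direct optimizer.
No scale-factor normalization is applied — the fit diagnoses, it does not
adjust.

## Marker signatures

`anova_like()` tests each sufficiently expressed gene (non-zero in at
least `min_cells_expressing = 3` cells) for across-cluster differential
expression by one-way ANOVA on `log2(CPM + 1)`, with BH adjustment over
the tested genes only. This is deliberately a *functional* signature
detector — per-gene across-cluster signal plus FDR — not an emulation of
count-model tests; the implementation is a vectorized row-wise F
statistic, verified gene-by-gene against `stats::oneway.test`.
`top_markers()` ranks per-cluster by ascending FDR then descending F, and
`heatmap_export()` produces the display matrix (cells ordered by cluster,
genes by average-linkage hierarchical clustering of row-standardized
values; zero-variance rows standardize to zeros) plus per-gene per-cell
CPM tables.

## The synthetic generator

`generate_synthetic()` emulates the data regime the package is designed
for: negative-binomial UMI counts (dispersion 0.1, i.e. NB size 10) with
gene-wise log-normal baseline means (meanlog 0.5, sdlog 1.2 — a steep,
realistic mean-expression distribution), planted clusters with disjoint
marker sets at a configurable fold change, mito/ribo gene families with
flaggable symbols, and planted "stressed" cells. Stressed cells are
*constructed*, not sampled: their columns are overwritten with a profile
that detects ~25 genes (mostly mitochondrial, each at the detection
threshold of 3) plus a few sub-threshold counts, guaranteeing
detected genes < 100, total UMI < 100 and mitochondrial percentage > 50
exactly — so the QC filtering tests are set-equality tests, not
probabilistic ones.

The frozen presets (`easy2`, `easy3`, `easy5`, `null1`, `stressed_mix`)
use fold change 8 with 40–50 markers per cluster: strong, well-separated
structure. That is intentional — they validate the *machinery* (label
recovery, CSS calibration at the planted `k`, exact QC arithmetic), not
the hard frontier of clustering. Real droplet data additionally contain
ambient RNA, doublets, batch effects and continuous gradients, none of
which the generator emulates; passing these tests therefore demonstrates
correctness of the stability computation, not that any particular engine
will resolve subtle subpopulations in real tissue.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: presets of
100–500 cells and 1,500–2,500 genes, sweeps over `k` in 2–6 with `B = 100`
runs and 5–10 master seeds — sizes chosen so the entire suite reruns in
minutes on a laptop while leaving the statistical conclusions (k-recovery,
CSS ordering across `k`, null type-I control) stable across seeds.
Degenerate-input conventions are fixed explicitly: silhouette 0 for
singletons and identical points; single-cluster fallback with a warning
for all-identical matrices; `NA` (never 0) for undefined CSS and undefined
QC percentages; errors rather than empty matrices when filtering would
remove everything.

## Limitations

* CSS measures *stability under subsampling*, not biological truth: a
  consistently wrong partition (e.g. one driven by a batch effect) can be
  perfectly stable.
* The built-in engines are deliberately plain baselines; the package's
  claims are about the stability machinery around any engine, and
  similarity-learning or SNN-refinement internals of dedicated tools are
  intentionally out of scope.
* The Lorenz filter and the CSS aggregation rule are documented
  reconstructions of under-specified procedures, with the variants exposed
  as options.

## A minimal session

```{r example}
library(cellstab)

sim <- generate_synthetic(synthetic_presets("easy3"))
m <- filter_cells(sim$matrix)$matrix

spec <- clusterer_spec("kmeans_log", k = 3)
sweep_res <- css_sweep(m, spec, k_values = 2:6, B = 100, f = 0.1,
                       master_seed = 1)
sweep_res$summary
sweep_res$best_k

report <- run_stability(m, spec, B = 160, f = 0.1, master_seed = 1)
report
markers <- top_markers(anova_like(m, report$reference), per_cluster_n = 10)
```
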
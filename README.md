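# cellstab

Cluster stability assessment for single-cell RNA-seq.

Clustering partitions cells into putative subpopulations, and every
downstream claim (markers, annotations, comparisons) inherits those
boundaries — but a partition fitted to one sample of cells need not survive
a different sample. `cellstab` measures that fragility per cell with the
**Cell Stability Score (CSS)**: the data set is re-clustered `B` times after
random removal of a fraction `f` of cells, and each cell `i` is scored by

```
CSS(i) = mean over runs b retaining i of  J(i, b),
J(i, b) = |A ∩ B| / |A ∪ B|,
```

where `A` is `i`'s reference co-cluster set restricted to the retained
cells and `B` is the cluster containing `i` in run `b` (both include `i`,
so a defined CSS lies in (0, 1]). Alongside CSS the package computes
Hennig-style per-cluster bootstrap stability (mean best-match Jaccard per
reference cluster), per-cell silhouettes in the clustering space, and a
**CSS sweep** that picks the number of clusters `k` by maximizing mean CSS.

It is written for analysts who want cluster-quality evidence that is
per-cell, engine-agnostic and reproducible: two baseline engines are built
in (PCA + k-means++ on log10 counts; kNN-graph Louvain on log-normalized
counts), and any external clusterer plugs in through a callback. Supporting
modules cover 10x-style MTX / CSV / TSV count-matrix I/O, GTF gene
annotation with mitochondrial/ribosomal flagging, per-cell QC (detected
genes, total UMI, mito/ribo percentages), filtering with an audit trail, a
Lorenz/Gini low-complexity cell filter, a count–depth diagnostic,
ANOVA-based cluster signatures, and a deterministic synthetic-data
generator with planted clusters, markers and low-quality cells.

## Worked example

```r
library(cellstab)

sim <- generate_synthetic(synthetic_presets("easy3"))  # 3 planted clusters
m <- filter_cells(sim$matrix)$matrix                   # default QC rules
m
#> CountMatrix: 2000 genes x 300 cells (424383 nonzero entries)
#>   flagged genes: 20 mito, 100 ribo

spec <- clusterer_spec("kmeans_log", k = 3)
sw <- css_sweep(m, spec, k_values = 2:5, B = 100, f = 0.1, master_seed = 1)
sw$summary
#>   k mean_css median_css iqr_css mean_silhouette
#> 1 2    0.856      0.865  0.0395           0.432
#> 2 3    1.000      1.000  0.0000           0.634
#> 3 4    0.785      0.902  0.3195           0.462
#> 4 5    0.556      0.524  0.2166           0.285
sw$best_k
#> [1] 3
```

Mean CSS peaks — at 1.000, perfect persistence — exactly at the planted
`k = 3`: under-clustering (k = 2) forces two true groups to share a
cluster whose membership churns under perturbation, and over-clustering
(k = 4, 5) splits homogeneous groups along noise directions that reshuffle
every run. The silhouette column tracks the same ordering here but is much
less separated, which is why `best_k` is decided on CSS.

```r
report <- run_stability(m, spec, B = 160, f = 0.1, master_seed = 1)
report
#> StabilityReport: 300 cells, k = 3, B = 160, f = 0.10
#>   mean CSS 1.000 | median CSS 1.000 | mean silhouette 0.634
report$cluster_stability
#>   cluster stability n_runs
#> 1       1         1    160
#> 2       2         1    160
#> 3       3         1    160

top_markers(anova_like(m, report$reference), per_cluster_n = 3)
#> $cluster_1
#> [1] "Gene01051" "Gene01451" "Gene01421"
#> $cluster_2
#> [1] "Gene01816" "Gene01342" "Gene01760"
#> $cluster_3
#> [1] "Gene01826" "Gene00149" "Gene01490"
```

Per-cell scores live in `report$scores` (`cell_id`, `css`, `n_retained`,
`silhouette`); `violin_export()` reshapes them for violin plots and
`save_stability_report()` writes all artifacts plus a parameter JSON.

The same pipeline is scriptable end-to-end from a shell via the bundled
CLI (`inst/cli/cellstab`), whose subcommands (`simulate`, `qc`, `filter`,
`cluster`, `stability`, `sweep`, `markers`, `report`) each write a
reproducibility manifest (parameters, master seed, input digests, version)
next to their outputs.

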
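Package: cellstab
Title: Cluster Stability Assessment for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the robustness of single-cell RNA-seq clusterings with
    a per-cell Cell Stability Score (CSS): the data set is repeatedly
    re-clustered after random removal of a fraction of cells, and each cell is
    scored by the mean Jaccard similarity between its reference co-cluster set
    and the cluster it lands in across perturbed runs. Also provides
    Hennig-style per-cluster bootstrap stability, silhouette comparison, a CSS
    sweep for choosing the number of clusters, UMI count-matrix quality
    control (detected genes, mitochondrial/ribosomal gene fractions, Lorenz
    low-complexity outlier filtering, count-depth diagnostics), cluster-marker
    signature detection, a deterministic synthetic count generator with
    planted clusters, and a command-line interface with reproducibility
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    mclust,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
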
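#' Counts per million
#'
#' `cpm[g, c] = 1e6 * count[g, c] / total_umi(c)`. Every column of the
#' result sums to one million.
#'
#' @param m A [CountMatrix] in which every cell has positive total UMI.
#' @return Dense numeric genes-by-cells matrix.
#' @export
cpm <- function(m) {
  validate_count_matrix(m)
  tot <- as.numeric(Matrix::colSums(m$counts))
  if (any(tot == 0)) {
    stop("CPM undefined for zero-total-UMI cell(s): ",
         paste(m$cell_ids[tot == 0], collapse = ", "), call. = FALSE)
  }
  sweep(as.matrix(m$counts), 2, 1e6 / tot, `*`)
}

# Vectorized one-way ANOVA across all genes at once: F = MSB/MSW on the
# rows of Y given group labels g. Rows with zero within- and zero
# between-group variance get F = 0, p = 1.
.row_anova <- function(Y, g) {
  g <- as.integer(g)
  k <- max(g)
  n <- ncol(Y)
  sizes <- tabulate(g, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), g)] <- 1
  gs <- Y %*% ind                       # per-group sums
  gm <- sweep(gs, 2, sizes, `/`)        # per-group means
  grand <- rowSums(Y) / n
  ssb <- rowSums(sweep(gm, 2, sizes, `*`) * gm) - n * grand^2
  ssw <- pmax(rowSums(Y^2) - rowSums(sweep(gm^2, 2, sizes, `*`)), 0)
  ssb <- pmax(ssb, 0)
  # cancellation guard: sums of squares below float noise are true zeros
  eps <- 1e-10 * (rowSums(Y^2) + 1)
  ssb[ssb < eps] <- 0
  ssw[ssw < eps] <- 0
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.finite(f), stats::pf(f, k - 1, n - k, lower.tail = FALSE),
              0)
  p[f == 0] <- 1
  list(statistic = f, p_value = p, group_means = gm)
}

#' Cluster-signature testing by one-way ANOVA on log2(CPM + 1)
#'
#' Tests every sufficiently expressed gene for differential expression
#' across the clusters of `part` with a one-way ANOVA on `log2(CPM + 1)`,
#' followed by Benjamini-Hochberg adjustment over the tested genes. This is
#' a functional cluster-signature detector (across-cluster signal plus
#' FDR), not a numerical reproduction of count-model tests.
#'
#' @param m A [CountMatrix].
#' @param part A [partition()] with `k >= 2` and every cluster of size >= 2.
#' @param min_cells_expressing Genes with a non-zero count in fewer cells
#'   are not tested (flagged `tested = FALSE`, statistics `NA`).
#' @return data.frame with `gene_id`, `tested`, `statistic`, `p_value`,
#'   `fdr`, `best_cluster` and per-cluster mean CPM columns
#'   (`mean_cpm.<cluster>`).
#' @export
anova_like <- function(m, part, min_cells_expressing = 3) {
  stopifnot(inherits(part, "Partition"))
  if (!identical(part$cell_ids, m$cell_ids)) {
    stop("partition does not cover the matrix cells in order", call. = FALSE)
  }
  if (part$k < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (any(tabulate(part$labels, part$k) < 2L)) {
    stop("every cluster needs >= 2 cells for a within-group variance",
         call. = FALSE)
  }
  cpm_mat <- cpm(m)
  expressed <- rowSums(as.matrix(m$counts) > 0) >= min_cells_expressing
  Y <- log2(cpm_mat + 1)
  res <- data.frame(gene_id = m$gene_ids, tested = expressed,
                    statistic = NA_real_, p_value = NA_real_,
                    fdr = NA_real_, best_cluster = NA_integer_)
  # per-cluster mean CPM reported for all genes
  cl_means <- t(apply(cpm_mat, 1, function(x) tapply(x, part$labels, mean)))
  colnames(cl_means) <- paste0("mean_cpm.", seq_len(part$k))
  if (any(expressed)) {
    fit <- .row_anova(Y[expressed, , drop = FALSE], part$labels)
    res$statistic[expressed] <- fit$statistic
    res$p_value[expressed] <- fit$p_value
    res$fdr[expressed] <- stats::p.adjust(fit$p_value, method = "BH")
    res$best_cluster[expressed] <-
      max.col(cl_means[expressed, , drop = FALSE], ties.method = "first")
  }
  cbind(res, as.data.frame(cl_means))
}

#' Select top marker genes per cluster
#'
#' Per cluster: the tested genes whose highest mean expression falls in that
#' cluster and whose FDR passes the threshold, ranked by ascending FDR then
#' descending statistic (deterministic ordering), optionally capped.
#'
#' @param results Output of [anova_like()].
#' @param per_cluster_n Optional cap on markers per cluster.
#' @param fdr_threshold Keep genes with `fdr < fdr_threshold` (default 0.05).
#' @return Named list (one element per cluster) of gene-id vectors; empty
#'   vectors allowed.
#' @export
top_markers <- function(results, per_cluster_n = NULL, fdr_threshold = 0.05) {
  stopifnot(nrow(results) > 0)
  clusters <- sort(unique(stats::na.omit(results$best_cluster)))
  out <- lapply(clusters, function(cl) {
    sub <- results[!is.na(results$fdr) & results$best_cluster == cl &
                     results$fdr < fdr_threshold, , drop = FALSE]
    sub <- sub[order(sub$fdr, -sub$statistic, sub$gene_id), , drop = FALSE]
    ids <- sub$gene_id
    if (!is.null(per_cluster_n)) ids <- utils::head(ids, per_cluster_n)
    ids
  })
  names(out) <- paste0("cluster_", clusters)
  out
}

#' Heat-map matrix and per-gene cell-expression tables
#'
#' Prepares the display artifacts for a marker heat map: cells ordered by
#' cluster label then barcode; genes ordered by average-linkage hierarchical
#' clustering (Euclidean) of row-standardized `log2(CPM + 1)`; zero-variance
#' rows standardize to zeros by convention. Also emits, per requested gene,
#' a `(cell_id, cluster, cpm)` table for per-cell expression plots.
#'
#' @param m A [CountMatrix].
#' @param part A [partition()] over the cells of `m`.
#' @param genes Character vector of gene ids to display (must exist).
#' @return List with `matrix` (ordered standardized values, genes x cells),
#'   `cell_order`, `gene_order`, and `cell_tables` (named list of per-gene
#'   data.frames).
#' @export
heatmap_export <- function(m, part, genes) {
  stopifnot(inherits(part, "Partition"))
  missing <- setdiff(genes, m$gene_ids)
  if (length(missing)) {
    stop("genes not present in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cpm_mat <- cpm(m)
  cell_order <- order(part$labels, part$cell_ids)
  Y <- log2(cpm_mat[match(genes, m$gene_ids), , drop = FALSE] + 1)
  Z <- t(apply(Y, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  rownames(Z) <- genes
  gene_order <- if (length(genes) > 2) {
    stats::hclust(stats::dist(Z), method = "average")$order
  } else {
    seq_along(genes)
  }
  ordered <- Z[gene_order, cell_order, drop = FALSE]
  colnames(ordered) <- part$cell_ids[cell_order]
  tables <- lapply(genes, function(g) {
    data.frame(cell_id = part$cell_ids[cell_order],
               cluster = part$labels[cell_order],
               cpm = cpm_mat[match(g, m$gene_ids), cell_order])
  })
  names(tables) <- genes
  list(matrix = ordered,
       cell_order = part$cell_ids[cell_order],
       gene_order = genes[gene_order],
       cell_tables = tables)
}
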
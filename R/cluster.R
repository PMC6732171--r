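#' Construct a Partition (cell -> cluster assignment)
#'
#' Labels are normalized to consecutive integers `1..k` in order of first
#' appearance; label values carry no cross-run meaning (cluster identity is
#' co-membership, not the integer).
#'
#' @param cell_ids Character vector of cell barcodes.
#' @param labels Vector of cluster labels, one per cell.
#' @return Object of class `Partition` with fields `cell_ids`, `labels`, `k`.
#' @export
partition <- function(cell_ids, labels) {
  stopifnot(length(cell_ids) == length(labels), !anyDuplicated(cell_ids))
  lab <- as.integer(factor(as.character(labels),
                           levels = unique(as.character(labels))))
  structure(list(cell_ids = as.character(cell_ids), labels = lab,
                 k = length(unique(lab))),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d cells in %d clusters (sizes: %s)\n",
              length(x$cell_ids), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Describe a clustering engine
#'
#' A `ClustererSpec` pins down everything a clustering run depends on, so
#' the stability machinery can treat engines interchangeably:
#' * `kmeans_log` — k-means (k-means++ seeding, 10 restarts, best inertia)
#'   on the top principal components of the transformed matrix; `k`
#'   required. Default transform `log10p1`, the convention of k-means-style
#'   single-cell engines operating on log10 counts.
#' * `graph_community` — symmetrized unweighted kNN graph (Euclidean in PCA
#'   space) with Louvain modularity communities; `k` emerges from the data.
#'   Default transform `lognorm10k` (global-scaling log normalization,
#'   factor 10,000).
#' * `external` — a user-supplied function `function(m, k, seed)` returning
#'   one label per cell of `m`, honoring determinism for a fixed seed.
#'
#' @param engine `"kmeans_log"`, `"graph_community"` or `"external"`.
#' @param k Number of clusters (required for `kmeans_log`, ignored by
#'   `graph_community`).
#' @param transform `"log10p1"`, `"lognorm10k"` or `"none"`; engine default
#'   used when `NULL`.
#' @param n_neighbors kNN graph degree for `graph_community` (>= 2).
#' @param n_pcs Number of principal components both engines cluster on.
#' @param seed Integer RNG seed; every run is deterministic given it.
#' @param fn Callback for `engine = "external"`.
#' @return Object of class `ClustererSpec`.
#' @export
clusterer_spec <- function(engine = c("kmeans_log", "graph_community",
                                      "external"),
                           k = NULL, transform = NULL, n_neighbors = 15,
                           n_pcs = 10, seed = 1, fn = NULL) {
  engine <- match.arg(engine)
  if (is.null(transform)) {
    transform <- switch(engine, kmeans_log = "log10p1",
                        graph_community = "lognorm10k", external = "none")
  }
  transform <- match.arg(transform, c("log10p1", "lognorm10k", "none"))
  if (engine == "kmeans_log") {
    if (is.null(k) || k < 2) stop("kmeans_log requires k >= 2", call. = FALSE)
  }
  if (engine == "external" && !is.function(fn)) {
    stop("engine 'external' requires a callback function fn(m, k, seed)",
         call. = FALSE)
  }
  if (n_neighbors < 2) stop("n_neighbors must be >= 2", call. = FALSE)
  structure(list(engine = engine, k = if (!is.null(k)) as.integer(k),
                 transform = transform, n_neighbors = as.integer(n_neighbors),
                 n_pcs = as.integer(n_pcs), seed = as.integer(seed), fn = fn),
            class = "ClustererSpec")
}

#' Transform raw counts for clustering
#'
#' * `log10p1`: `log10(count + 1)`.
#' * `lognorm10k`: `ln(1 + 10000 * count / total_umi(cell))` — global
#'   scaling log-normalization with scale factor 10,000.
#' * `none`: counts cast to numeric.
#'
#' @param m A [CountMatrix].
#' @param transform One of the three transform names.
#' @return Dense numeric genes-by-cells matrix.
#' @export
transform_counts <- function(m, transform = c("log10p1", "lognorm10k",
                                              "none")) {
  transform <- match.arg(transform)
  validate_count_matrix(m)
  dense <- as.matrix(m$counts)
  switch(transform,
    log10p1 = log10(dense + 1),
    lognorm10k = {
      tot <- colSums(dense)
      if (any(tot == 0)) {
        stop("lognorm10k undefined for zero-total-UMI cell(s): ",
             paste(m$cell_ids[tot == 0], collapse = ", "), call. = FALSE)
      }
      log1p(sweep(dense, 2, 1e4 / tot, `*`))
    },
    none = dense)
}

# PCA scores of cells (rows = cells). Uses the n x n Gram-matrix eigenroute,
# which is much cheaper than a full SVD when genes >> cells. Component signs
# are fixed so the largest-magnitude coordinate of each score column is
# positive (determinism across BLAS quirks).
.pca_scores <- function(X, n_pcs) {
  Y <- t(X)                                  # cells x genes
  Y <- sweep(Y, 2, colMeans(Y), `-`)
  G <- tcrossprod(Y)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values[1], 0) * 1e-10
  p <- min(n_pcs, sum(pos), nrow(Y) - 1L)
  if (p < 1L) return(matrix(0, nrow(Y), 1))
  sc <- e$vectors[, seq_len(p), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(p)], 0)), p)
  for (j in seq_len(p)) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  rownames(sc) <- rownames(Y)
  sc
}

# k-means++ seeding over rows of X; returns row indices of the k centers.
.kmeanspp <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], `-`)^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # fewer distinct points than centers; reuse arbitrary distinct rows
      centers[j:k] <- rep(centers[1], k - j + 1L)
      return(centers)
    }
    centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ], `-`)^2))
  }
  centers
}

.cluster_kmeans <- function(scores, k, n_restarts = 10L) {
  distinct <- unique(scores)
  if (nrow(distinct) < k) {
    warning("fewer distinct cell profiles (", nrow(distinct),
            ") than k = ", k, "; clustering distinct profiles only",
            call. = FALSE)
    if (nrow(distinct) == 1L) {
      return(rep(1L, nrow(scores)))
    }
    k <- nrow(distinct)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- scores[.kmeanspp(scores, k), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(scores, centers = init,
                                         iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

.cluster_graph <- function(scores, n_neighbors) {
  n <- nrow(scores)
  if (n_neighbors >= n) {
    stop("n_neighbors must be smaller than the number of cells",
         call. = FALSE)
  }
  D <- as.matrix(stats::dist(scores))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(n_neighbors + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  igraph::membership(igraph::cluster_louvain(g))
}

#' Cluster cells with a pluggable engine
#'
#' Runs the engine described by `spec` on the cells of `m` and returns a
#' [partition()] covering exactly `m$cell_ids`. Deterministic given
#' `(m, spec)` — all randomness derives from `spec$seed`. Degenerate input
#' in which every cell is identical yields a single-cluster partition with a
#' warning rather than an error, so perturbation runs never abort.
#'
#' @param m A [CountMatrix] with at least 2 cells.
#' @param spec A [clusterer_spec()].
#' @return A `Partition`.
#' @export
cluster_cells <- function(m, spec) {
  stopifnot(inherits(spec, "ClustererSpec"))
  validate_count_matrix(m)
  n <- ncol(m$counts)
  if (n < 2L) stop("clustering needs at least 2 cells", call. = FALSE)
  if (!is.null(spec$k) && spec$k > n) {
    stop("k = ", spec$k, " exceeds the number of cells (", n, ")",
         call. = FALSE)
  }
  set.seed(spec$seed)
  if (spec$engine == "external") {
    labels <- spec$fn(m, spec$k, spec$seed)
    if (length(labels) != n) {
      stop("external clusterer returned ", length(labels),
           " labels for ", n, " cells", call. = FALSE)
    }
    return(partition(m$cell_ids, labels))
  }
  X <- transform_counts(m, spec$transform)
  scores <- .pca_scores(X, spec$n_pcs)
  labels <- switch(spec$engine,
    kmeans_log = .cluster_kmeans(scores, spec$k),
    graph_community = .cluster_graph(scores, spec$n_neighbors))
  partition(m$cell_ids, labels)
}

#' Estimate the number of clusters from graph communities
#'
#' Runs the `graph_community` engine and reports the number of communities
#' it finds — a data-driven proposal for `k` to feed into k-means style
#' engines or a [css_sweep()].
#'
#' @param m A [CountMatrix].
#' @param spec A [clusterer_spec()]; its engine is forced to
#'   `graph_community`.
#' @return Positive integer.
#' @export
propose_k <- function(m, spec = clusterer_spec("graph_community")) {
  spec$engine <- "graph_community"
  if (is.null(spec$transform)) spec$transform <- "lognorm10k"
  cluster_cells(m, spec)$k
}
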
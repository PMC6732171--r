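# Deterministic synthetic UMI counts with planted structure. Counts are
# negative binomial with gene-wise log-normal baseline means; each cluster
# gets a disjoint set of marker genes whose mean is multiplied by a fold
# change in that cluster. Gene families carry flaggable symbols (mt-*,
# Rps*/Rpl*). "Stressed" cells — the low-information, high-mitochondrial
# profile seen in droplet QC — are constructed by post-hoc column edits so
# their QC properties (detected genes < 100, total UMI < 100, mito gene
# percentage > 50) hold exactly, not just in expectation.

#' Specify a synthetic count matrix
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param k_true Number of planted clusters (1 = no structure).
#' @param cluster_proportions Cluster size fractions (default equal); must
#'   sum to 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline negative-binomial mean.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (variance = mu + phi * mu^2).
#' @param n_markers_per_cluster Planted marker genes per cluster (disjoint
#'   sets, drawn outside the mito/ribo families).
#' @param marker_fold_change Mean fold change of a marker in its cluster
#'   (> 1).
#' @param frac_mito_genes,frac_ribo_genes Fractions of genes given
#'   mitochondrial (`mt-*`) / ribosomal (`Rps*`/`Rpl*`) symbols.
#' @param n_stressed_cells Number of planted low-quality cells.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return Object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_cells, n_genes, k_true = 1,
                           cluster_proportions = NULL,
                           baseline_meanlog = 0.5, baseline_sdlog = 1.2,
                           nb_dispersion = 0.1,
                           n_markers_per_cluster = 0,
                           marker_fold_change = 8,
                           frac_mito_genes = 0.01, frac_ribo_genes = 0.05,
                           n_stressed_cells = 0, seed = 1) {
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / k_true, k_true)
  }
  spec <- structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         k_true = as.integer(k_true),
         cluster_proportions = cluster_proportions,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         nb_dispersion = nb_dispersion,
         n_markers_per_cluster = as.integer(n_markers_per_cluster),
         marker_fold_change = marker_fold_change,
         frac_mito_genes = frac_mito_genes,
         frac_ribo_genes = frac_ribo_genes,
         n_stressed_cells = as.integer(n_stressed_cells),
         seed = as.integer(seed)),
    class = "SyntheticSpec")
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (abs(sum(spec$cluster_proportions) - 1) > 1e-8 ||
      length(spec$cluster_proportions) != spec$k_true) {
    stop("cluster_proportions must have k_true entries summing to 1",
         call. = FALSE)
  }
  if (spec$n_markers_per_cluster > 0 && spec$marker_fold_change <= 1) {
    stop("marker_fold_change must exceed 1", call. = FALSE)
  }
  if (spec$nb_dispersion <= 0) stop("nb_dispersion must be positive",
                                    call. = FALSE)
  n_mito <- round(spec$frac_mito_genes * spec$n_genes)
  n_ribo <- round(spec$frac_ribo_genes * spec$n_genes)
  free <- spec$n_genes - n_mito - n_ribo
  if (spec$k_true * spec$n_markers_per_cluster > free) {
    stop("not enough genes for the requested marker sets", call. = FALSE)
  }
  if (spec$n_stressed_cells > 0 && n_mito < 8) {
    stop("stressed cells need >= 8 mitochondrial genes; raise frac_mito_genes",
         call. = FALSE)
  }
  if (spec$n_stressed_cells >= spec$n_cells) {
    stop("n_stressed_cells must be below n_cells", call. = FALSE)
  }
  spec
}

#' Generate a synthetic count matrix with planted truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (an annotated [CountMatrix]) and `truth`
#'   (list: `labels` named integer vector, `marker_genes` list per cluster,
#'   `stressed_cell_ids`).
#' @export
generate_synthetic <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  n_mito <- round(spec$frac_mito_genes * spec$n_genes)
  n_ribo <- round(spec$frac_ribo_genes * spec$n_genes)
  symbols <- sprintf("Gene%05d", seq_len(spec$n_genes))
  mito_idx <- seq_len(n_mito)
  ribo_idx <- n_mito + seq_len(n_ribo)
  symbols[mito_idx] <- sprintf("mt-M%02d", seq_len(n_mito))
  symbols[ribo_idx] <- sprintf("%s%03d",
                               rep(c("Rps", "Rpl"), length.out = n_ribo),
                               seq_len(n_ribo))
  # cluster sizes from proportions (largest-remainder rounding)
  sizes <- floor(spec$cluster_proportions * spec$n_cells)
  rem <- spec$n_cells - sum(sizes)
  if (rem > 0) {
    extra <- order(spec$cluster_proportions * spec$n_cells - sizes,
                   decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  labels <- rep(seq_len(spec$k_true), times = sizes)
  cell_ids <- sprintf("cell_%04d", seq_len(spec$n_cells))

  free_genes <- setdiff(seq_len(spec$n_genes), c(mito_idx, ribo_idx))
  markers <- list()
  if (spec$n_markers_per_cluster > 0 && spec$k_true > 1) {
    pool <- sample(free_genes,
                   spec$k_true * spec$n_markers_per_cluster)
    markers <- split(pool, rep(seq_len(spec$k_true),
                               each = spec$n_markers_per_cluster))
  }

  base_mu <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog,
                           spec$baseline_sdlog)
  size <- 1 / spec$nb_dispersion
  counts <- matrix(0L, spec$n_genes, spec$n_cells)
  for (cl in seq_len(spec$k_true)) {
    cols <- which(labels == cl)
    mu <- base_mu
    if (length(markers) >= cl) {
      mu[markers[[cl]]] <- mu[markers[[cl]]] * spec$marker_fold_change
    }
    counts[, cols] <- stats::rnbinom(spec$n_genes * length(cols),
                                     mu = mu, size = size)
  }

  stressed <- character(0)
  if (spec$n_stressed_cells > 0) {
    idx <- seq(spec$n_cells - spec$n_stressed_cells + 1L, spec$n_cells)
    stressed <- cell_ids[idx]
    n_mito_det <- min(n_mito, 14L)
    n_other_det <- max(4L, n_mito_det - 6L)   # keeps mito fraction > 1/2
    for (j in idx) {
      col <- integer(spec$n_genes)
      col[sample(mito_idx, n_mito_det)] <- 3L
      col[sample(free_genes, n_other_det)] <- 3L
      col[sample(which(col == 0L), 8L)] <- 1L  # sub-threshold noise counts
      counts[, j] <- col
    }
  }

  m <- CountMatrix(counts, gene_ids = symbols, cell_ids = cell_ids,
                   gene_symbols = symbols)
  m <- annotate_genes(m, NULL)
  list(matrix = m,
       truth = list(labels = stats::setNames(labels, cell_ids),
                    marker_genes = lapply(markers,
                                          function(i) symbols[i]),
                    stressed_cell_ids = stressed))
}

#' Frozen synthetic presets
#'
#' Named, frozen parameterizations used throughout the tests and examples:
#' `easy2`/`easy3`/`easy5` — strongly separated planted clusters (fold
#' change 8, NB dispersion 0.1); `null1` — one homogeneous population, no
#' structure; `stressed_mix` — `easy3`-like with 20 planted low-quality
#' cells.
#'
#' @param name One of `"easy2"`, `"easy3"`, `"easy5"`, `"null1"`,
#'   `"stressed_mix"`.
#' @return A [synthetic_spec()].
#' @export
synthetic_presets <- function(name) {
  presets <- list(
    easy2 = synthetic_spec(n_cells = 100, n_genes = 1500, k_true = 2,
                           n_markers_per_cluster = 50,
                           marker_fold_change = 8, seed = 1),
    easy3 = synthetic_spec(n_cells = 300, n_genes = 2000, k_true = 3,
                           n_markers_per_cluster = 50,
                           marker_fold_change = 8, seed = 1),
    easy5 = synthetic_spec(n_cells = 500, n_genes = 2500, k_true = 5,
                           n_markers_per_cluster = 40,
                           marker_fold_change = 8, seed = 1),
    null1 = synthetic_spec(n_cells = 200, n_genes = 1500, k_true = 1,
                           seed = 1),
    stressed_mix = synthetic_spec(n_cells = 300, n_genes = 2000, k_true = 3,
                                  n_markers_per_cluster = 50,
                                  marker_fold_change = 8,
                                  n_stressed_cells = 20, seed = 1))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Write a synthetic data set as a 10x-style directory plus truth JSON
#'
#' @param sim Output of [generate_synthetic()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  save_counts(sim$matrix, dir, format = "mtx_dir")
  jsonlite::write_json(
    list(labels = as.list(sim$truth$labels),
         marker_genes = sim$truth$marker_genes,
         stressed_cell_ids = sim$truth$stressed_cell_ids),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
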
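# Stability core: perturbed re-clustering, per-cell CSS, Hennig-style
# per-cluster stability, silhouette, and the CSS sweep over candidate k.
#
# CSS formula: for cell i and perturbation run b retaining i, let
#   A = (reference co-cluster set of i) ∩ retained_b    (includes i)
#   B = run-b cluster containing i                      (includes i)
# then J(i,b) = |A ∩ B| / |A ∪ B| and CSS(i) is the mean of J(i,b) over the
# runs retaining i. Self-membership makes every defined CSS strictly
# positive. An optional thresholded variant reports the fraction of runs
# with J(i,b) >= a cutoff instead of the mean.

#' Perturbed re-clustering runs
#'
#' Produces `B` perturbation runs: run `b` removes a uniformly random
#' `floor(f * n)`-subset of cells (so `ceiling((1 - f) * n)` are retained)
#' and re-clusters the retained submatrix. All randomness of run `b` derives
#' from the child seed `master_seed + b`, so runs are order-independent and
#' the whole procedure is reproducible bit-for-bit from `master_seed`.
#'
#' @param m A [CountMatrix].
#' @param spec A [clusterer_spec()]; its seed is overridden per run.
#' @param B Number of perturbation runs (>= 1; >= 100 recommended for a
#'   stable CSS estimate, default 160).
#' @param f Fraction of cells removed per run, in (0, 1); default 0.1.
#' @param master_seed Integer master seed.
#' @return List of `PermutationRun` objects with fields `run_index`, `seed`,
#'   `retained_cell_ids`, `partition`.
#' @export
permute_and_cluster <- function(m, spec, B = 160, f = 0.1, master_seed = 1) {
  validate_count_matrix(m)
  stopifnot(inherits(spec, "ClustererSpec"), B >= 1)
  if (!is.numeric(f) || f <= 0 || f >= 1) {
    stop("f must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- ncol(m$counts)
  n_keep <- n - floor(f * n)
  minimum <- max(if (!is.null(spec$k)) spec$k else 2L,
                 if (spec$engine == "graph_community")
                   spec$n_neighbors + 1L else 2L)
  if (n_keep < minimum) {
    stop("retained set of ", n_keep, " cells is below the clusterer minimum (",
         minimum, ")", call. = FALSE)
  }
  lapply(seq_len(B), function(b) {
    child <- as.integer(master_seed + b)
    set.seed(child)
    retained <- sort(sample.int(n, n_keep))
    run_spec <- spec
    run_spec$seed <- child
    part <- cluster_cells(m[, retained], run_spec)
    structure(list(run_index = b, seed = child,
                   retained_cell_ids = m$cell_ids[retained],
                   partition = part),
              class = "PermutationRun")
  })
}

# Per-run Jaccard bookkeeping shared by CSS and Hennig stability: for a run,
# cross-tabulate reference labels (restricted to retained cells) against run
# labels. |A∩B| for a cell in reference cluster r and run cluster d is the
# table entry n[r,d]; |A∪B| = a_r + b_d - n[r,d].
.run_crosstab <- function(reference, run) {
  ref_lab <- reference$labels
  names(ref_lab) <- reference$cell_ids
  rc <- run$partition$cell_ids
  if (!all(rc %in% reference$cell_ids)) {
    stop("run retains cells absent from the reference partition",
         call. = FALSE)
  }
  r <- unname(ref_lab[rc])
  d <- run$partition$labels
  list(cells = rc, r = r, d = d,
       n_rd = table(factor(r, levels = seq_len(reference$k)),
                    factor(d, levels = seq_len(run$partition$k))),
       a_r = tabulate(r, reference$k),
       b_d = tabulate(d, run$partition$k))
}

#' Per-cell Cell Stability Score (CSS)
#'
#' For every cell, the mean Jaccard similarity — across the perturbation
#' runs retaining it — between its reference co-cluster set (restricted to
#' the retained cells) and the cluster it joins in the run. CSS is 1 when
#' the cell's neighbourhood is perfectly persistent and decreases towards 0
#' as perturbation scatters it; it is strictly positive wherever defined
#' (self-membership) and `NA` for cells never retained.
#'
#' @param reference A [partition()] over all cells (the unperturbed
#'   clustering that anchors "persistence").
#' @param runs A list of runs from [permute_and_cluster()].
#' @param threshold Optional Jaccard cutoff: when supplied, the score is the
#'   fraction of retaining runs with `J(i,b) >= threshold` instead of the
#'   mean Jaccard (variant scoring; the mean is the primary definition).
#' @return data.frame with `cell_id`, `css`, `n_retained`.
#' @export
cell_stability_score <- function(reference, runs, threshold = NULL) {
  stopifnot(inherits(reference, "Partition"))
  cells <- reference$cell_ids
  acc <- stats::setNames(numeric(length(cells)), cells)
  nret <- stats::setNames(integer(length(cells)), cells)
  for (run in runs) {
    ct <- .run_crosstab(reference, run)
    inter <- ct$n_rd[cbind(ct$r, ct$d)]
    J <- inter / (ct$a_r[ct$r] + ct$b_d[ct$d] - inter)
    contrib <- if (is.null(threshold)) J else as.numeric(J >= threshold)
    acc[ct$cells] <- acc[ct$cells] + contrib
    nret[ct$cells] <- nret[ct$cells] + 1L
  }
  data.frame(cell_id = cells,
             css = ifelse(nret > 0, acc / pmax(nret, 1L), NA_real_),
             n_retained = as.integer(nret), row.names = NULL)
}

#' Per-cluster stability (Hennig-style)
#'
#' For each reference cluster `C` and run `b`, the maximum Jaccard overlap
#' between `C` restricted to the retained cells and any cluster of the run;
#' the cluster's stability is the mean of these maxima over the runs in
#' which `C` is represented. This is the clusterwise bootstrap-stability
#' assessment of Hennig, applied to the random-removal perturbation scheme.
#'
#' @inheritParams cell_stability_score
#' @return data.frame with `cluster`, `stability`, `n_runs` (runs where the
#'   cluster was represented; stability is `NA` when that is zero).
#' @export
cluster_stability <- function(reference, runs) {
  stopifnot(inherits(reference, "Partition"))
  K <- reference$k
  acc <- numeric(K)
  nrun <- integer(K)
  for (run in runs) {
    ct <- .run_crosstab(reference, run)
    for (r in seq_len(K)) {
      if (ct$a_r[r] == 0L) next
      J <- ct$n_rd[r, ] / (ct$a_r[r] + ct$b_d - ct$n_rd[r, ])
      acc[r] <- acc[r] + max(J)
      nrun[r] <- nrun[r] + 1L
    }
  }
  data.frame(cluster = seq_len(K),
             stability = ifelse(nrun > 0, acc / pmax(nrun, 1L), NA_real_),
             n_runs = nrun)
}

#' Silhouette widths from a distance object
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` computed via
#' [cluster::silhouette()], with two degenerate conventions applied:
#' singleton-cluster cells get `s = 0`, and cells with `a = b = 0` (e.g. all
#' points identical) get `s = 0` instead of `NaN`.
#'
#' @param d A [stats::dist] object or square distance matrix.
#' @param labels Integer cluster labels (k >= 2).
#' @return Numeric vector of silhouette widths in `[-1, 1]`.
#' @export
silhouette_values <- function(d, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("silhouette undefined for a single cluster", call. = FALSE)
  }
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  sil <- cluster::silhouette(labels, dist = d)
  s <- sil[, "sil_width"]
  s[!is.finite(s)] <- 0
  as.numeric(s)
}

#' Per-cell silhouette scores in the clustering space
#'
#' Euclidean distances are taken in the same transformed/PCA space the
#' clustering engine used, so silhouettes are comparable across `k`.
#'
#' @param m A [CountMatrix].
#' @param part A [partition()] over the cells of `m` with `k >= 2`.
#' @param spec The [clusterer_spec()] whose space should be used.
#' @return data.frame with `cell_id`, `silhouette`.
#' @export
silhouette_scores <- function(m, part, spec) {
  stopifnot(inherits(part, "Partition"))
  if (!identical(part$cell_ids, m$cell_ids)) {
    stop("partition does not cover the matrix cells in order", call. = FALSE)
  }
  X <- transform_counts(m, spec$transform)
  scores <- .pca_scores(X, spec$n_pcs)
  data.frame(cell_id = m$cell_ids,
             silhouette = silhouette_values(stats::dist(scores),
                                            part$labels))
}

#' Full stability analysis for one clustering configuration
#'
#' Clusters the full matrix (the reference), runs `B` perturbed
#' re-clusterings, and assembles per-cell CSS, per-cell silhouette and
#' per-cluster stability into a `StabilityReport`.
#'
#' @inheritParams permute_and_cluster
#' @param silhouette Compute per-cell silhouettes (needs reference k >= 2).
#' @return `StabilityReport`: list with `reference` (Partition), `scores`
#'   (per-cell data.frame: `cell_id`, `css`, `n_retained`, `silhouette`),
#'   `cluster_stability` (per-cluster data.frame) and `params`.
#' @export
run_stability <- function(m, spec, B = 160, f = 0.1, master_seed = 1,
                          silhouette = TRUE) {
  ref_spec <- spec
  ref_spec$seed <- as.integer(master_seed)
  reference <- cluster_cells(m, ref_spec)
  runs <- permute_and_cluster(m, spec, B = B, f = f,
                              master_seed = master_seed)
  scores <- cell_stability_score(reference, runs)
  if (silhouette && reference$k >= 2L) {
    scores$silhouette <- silhouette_scores(m, reference, spec)$silhouette
  } else {
    scores$silhouette <- NA_real_
  }
  structure(
    list(reference = reference,
         scores = scores,
         cluster_stability = cluster_stability(reference, runs),
         params = list(engine = spec$engine, k = spec$k,
                       transform = spec$transform, n_pcs = spec$n_pcs,
                       n_neighbors = spec$n_neighbors, B = as.integer(B),
                       f = f, master_seed = as.integer(master_seed),
                       run_seeds = as.integer(master_seed + seq_len(B)))),
    class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  ok <- !is.na(x$scores$css)
  cat(sprintf("StabilityReport: %d cells, k = %d, B = %d, f = %.2f\n",
              nrow(x$scores), x$reference$k, x$params$B, x$params$f))
  cat(sprintf("  mean CSS %.3f | median CSS %.3f | mean silhouette %s\n",
              mean(x$scores$css[ok]), stats::median(x$scores$css[ok]),
              if (all(is.na(x$scores$silhouette))) "NA"
              else sprintf("%.3f", mean(x$scores$silhouette, na.rm = TRUE))))
  invisible(x)
}

#' CSS sweep over candidate numbers of clusters
#'
#' Runs a full stability analysis for every `k` in `k_values` (sharing the
#' master seed, so the same perturbation subsets are reused across `k` — a
#' paired comparison) and tabulates per-k CSS and silhouette summaries.
#' `best_k` maximizes mean CSS; ties go to the smallest k.
#'
#' @param m A [CountMatrix].
#' @param spec A [clusterer_spec()] template with a k-accepting engine.
#' @param k_values Integer vector of candidate cluster numbers.
#' @param B,f,master_seed As in [permute_and_cluster()].
#' @param keep_reports Keep the per-k `StabilityReport`s (memory-heavy).
#' @return List with `summary` (data.frame: `k`, `mean_css`, `median_css`,
#'   `iqr_css`, `mean_silhouette`), `best_k`, and optionally `reports`.
#' @export
css_sweep <- function(m, spec, k_values, B = 100, f = 0.1, master_seed = 1,
                      keep_reports = FALSE) {
  if (length(k_values) == 0L) stop("k_values must be non-empty", call. = FALSE)
  reports <- list()
  rows <- lapply(k_values, function(k) {
    sp <- spec
    sp$k <- as.integer(k)
    rep_k <- run_stability(m, sp, B = B, f = f, master_seed = master_seed)
    if (keep_reports) reports[[as.character(k)]] <<- rep_k
    css <- rep_k$scores$css[!is.na(rep_k$scores$css)]
    data.frame(k = as.integer(k),
               mean_css = mean(css),
               median_css = stats::median(css),
               iqr_css = stats::IQR(css),
               mean_silhouette = mean(rep_k$scores$silhouette, na.rm = TRUE))
  })
  summary <- do.call(rbind, rows)
  best <- summary$k[order(-summary$mean_css, summary$k)][1]
  out <- list(summary = summary, best_k = best)
  if (keep_reports) out$reports <- reports
  out
}

#' Long-format table for violin plots of CSS and silhouette
#'
#' @param report A `StabilityReport` (or list of them, e.g. from a sweep
#'   with `keep_reports = TRUE`).
#' @return data.frame with `cell_id`, `metric` (`"css"`/`"silhouette"`),
#'   `value`, `k`; undefined values are omitted and their count recorded in
#'   the `"n_undefined"` attribute.
#' @export
violin_export <- function(report) {
  reports <- if (inherits(report, "StabilityReport")) list(report) else report
  undefined <- 0L
  rows <- lapply(reports, function(r) {
    long <- rbind(
      data.frame(cell_id = r$scores$cell_id, metric = "css",
                 value = r$scores$css),
      data.frame(cell_id = r$scores$cell_id, metric = "silhouette",
                 value = r$scores$silhouette))
    long$k <- r$reference$k
    undefined <<- undefined + sum(is.na(long$value))
    long[!is.na(long$value), , drop = FALSE]
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), metric = character(),
               value = numeric(), k = integer())
  rownames(out) <- NULL
  attr(out, "n_undefined") <- undefined
  out
}

#' Persist a StabilityReport as plain-text artifacts
#'
#' Writes reference labels, per-cell scores, per-cluster stability and the
#' violin table as CSV, plus the parameter block (B, f, seeds, engine) as
#' JSON — everything needed to reproduce the run.
#'
#' @param report A `StabilityReport`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_stability_report <- function(report, dir) {
  stopifnot(inherits(report, "StabilityReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(cell_id = report$reference$cell_ids,
                              label = report$reference$labels),
                   file.path(dir, "reference_labels.csv"), row.names = FALSE)
  utils::write.csv(report$scores, file.path(dir, "cell_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cluster_stability,
                   file.path(dir, "cluster_stability.csv"), row.names = FALSE)
  utils::write.csv(violin_export(report), file.path(dir, "violin_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
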
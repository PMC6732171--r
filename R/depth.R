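# Count-depth diagnostic: per-gene median (L1) regression of log expression
# on log sequencing depth, with genes grouped by slope quantile. Diagnostic
# only; no scale-factor normalization is performed.

# L1 (tau = 0.5 quantile) straight-line fit by iteratively reweighted least
# squares: weights 1/max(|r|, eps) drive the weighted LS solution to the
# minimizer of sum |r|.
.l1_line <- function(x, y, max_iter = 200L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    w <- 1 / pmax(abs(r), 1e-8)
    new <- stats::lm.wfit(X, y, as.numeric(w))$coefficients
    new[is.na(new)] <- 0
    if (max(abs(new - beta)) < tol) {
      beta <- new
      break
    }
    beta <- new
  }
  unname(beta)
}

#' Count-depth relationship diagnostic
#'
#' Estimates, for every sufficiently expressed gene, how its measured
#' expression depends on a cell's total sequencing depth: a median
#' (quantile, tau = 0.5) regression of `log(count + 1)` on
#' `log(total_umi)`, fitted over the cells in which the gene is non-zero
#' (expression-conditional fitting). Genes are then aggregated into
#' `n_groups` equal-frequency groups by slope. A slope near 1 means counts
#' scale proportionally with depth; a slope near 0 means depth-independent
#' measurement.
#'
#' @param m A [CountMatrix] with at least 20 cells. Genes non-zero in fewer
#'   than 10 cells are skipped.
#' @param n_groups Number of slope-quantile groups (>= 2).
#' @return data.frame with `gene_id`, `slope`, `group`, plus a
#'   `"group_summary"` attribute giving the per-group median slope.
#' @export
count_depth_fit <- function(m, n_groups = 5) {
  validate_count_matrix(m)
  if (n_groups < 2) stop("n_groups must be >= 2", call. = FALSE)
  if (ncol(m$counts) < 20L) {
    stop("count_depth_fit needs at least 20 cells", call. = FALSE)
  }
  depth <- as.numeric(Matrix::colSums(m$counts))
  if (any(depth <= 0)) {
    stop("cells with zero total UMI present; filter before fitting",
         call. = FALSE)
  }
  logd <- log(depth)
  dense <- as.matrix(m$counts)
  fitted <- which(rowSums(dense > 0) >= 10L)
  slopes <- vapply(fitted, function(g) {
    nz <- dense[g, ] > 0
    x <- logd[nz]
    if (length(unique(x)) < 3L) return(NA_real_)
    .l1_line(x, log(dense[g, nz] + 1))[2]
  }, numeric(1))
  ok <- is.finite(slopes)
  res <- data.frame(gene_id = m$gene_ids[fitted][ok], slope = slopes[ok])
  if (nrow(res) == 0L) {
    stop("no gene passed the expression floor for fitting", call. = FALSE)
  }
  # equal-frequency split on slope rank; ties broken by order
  res$group <- as.integer(ceiling(rank(res$slope, ties.method = "first") *
                                    n_groups / nrow(res)))
  summary <- vapply(split(res$slope, res$group), stats::median, numeric(1))
  attr(res, "group_summary") <- data.frame(
    group = as.integer(names(summary)), median_slope = unname(summary))
  res
}
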
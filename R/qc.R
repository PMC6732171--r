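#' Per-cell detected genes and total UMI
#'
#' A gene is "detected" in a cell when it is supported by at least
#' `min_units` counts in that cell (suggested: 3 for UMI data, 5 for
#' read-count/smart-seq data).
#'
#' @param m A [CountMatrix].
#' @param min_units Positive integer detection threshold per gene per cell.
#' @return data.frame with columns `cell_id`, `detected_genes`, `total_umi`.
#' @export
genes_umi <- function(m, min_units = 3) {
  validate_count_matrix(m)
  if (!is.numeric(min_units) || length(min_units) != 1L || min_units < 1) {
    stop("min_units must be a single integer >= 1", call. = FALSE)
  }
  data.frame(
    cell_id = m$cell_ids,
    detected_genes = as.integer(Matrix::colSums(m$counts >= min_units)),
    total_umi = as.numeric(Matrix::colSums(m$counts))
  )
}

#' Per-cell mitochondrial/ribosomal gene percentages
#'
#' For each cell, the percentage of mitochondrial and of ribosomal genes
#' among the *detected* genes (gene-count fractions, not UMI fractions).
#' Cells detecting zero genes get `NA` percentages rather than a division by
#' zero. Requires gene flags, i.e. [annotate_genes()] must have been run.
#'
#' @inheritParams genes_umi
#' @param umi_based Compute percentages on UMI counts restricted to detected
#'   genes instead of detected-gene counts. Off by default; the gene-count
#'   definition is the primary one.
#' @return data.frame with `cell_id`, `detected_genes`, `total_umi`,
#'   `mito_gene_pct`, `ribo_gene_pct`.
#' @export
mito_ribo_umi <- function(m, min_units = 3, umi_based = FALSE) {
  if (is.null(m$gene_flags)) {
    stop("gene flags missing: run annotate_genes() first", call. = FALSE)
  }
  base <- genes_umi(m, min_units)
  det <- m$counts >= min_units
  mito <- m$gene_flags$is_mito
  ribo <- m$gene_flags$is_ribo
  if (umi_based) {
    kept <- m$counts * det
    denom <- Matrix::colSums(kept)
    mito_n <- Matrix::colSums(kept[mito, , drop = FALSE])
    ribo_n <- Matrix::colSums(kept[ribo, , drop = FALSE])
  } else {
    denom <- base$detected_genes
    mito_n <- Matrix::colSums(det[mito, , drop = FALSE])
    ribo_n <- Matrix::colSums(det[ribo, , drop = FALSE])
  }
  base$mito_gene_pct <- ifelse(denom > 0, 100 * as.numeric(mito_n) / denom, NA_real_)
  base$ribo_gene_pct <- ifelse(denom > 0, 100 * as.numeric(ribo_n) / denom, NA_real_)
  base
}

.audit_record <- function(rule, removed, params, what = "cell") {
  structure(list(rule_name = rule, removed = removed,
                 removed_what = what, parameters = params),
            class = "FilterAudit")
}

#' @export
print.FilterAudit <- function(x, ...) {
  cat(sprintf("FilterAudit: rule '%s' removed %d %ss\n",
              x$rule_name, length(x$removed), x$removed_what))
  invisible(x)
}

#' Filter low-quality cells (and optionally mito/ribo genes)
#'
#' Removes every cell failing *any* enabled rule, where all rules are
#' evaluated on the full input matrix. If `drop_mito_ribo_genes` is set,
#' flagged gene rows are removed after the cell rules have been evaluated.
#' Each rule's removals are recorded in an audit trail, in application order;
#' a cell failing several rules is attributed to the first one.
#'
#' @param m A [CountMatrix]; flags required when `max_mito_pct` or
#'   `drop_mito_ribo_genes` are used.
#' @param min_detected_genes Keep cells detecting at least this many genes
#'   (default 100).
#' @param min_total_umi Keep cells with at least this total UMI count
#'   (default 100).
#' @param max_mito_pct Optional ceiling on the mitochondrial detected-gene
#'   percentage; `NULL` disables the rule.
#' @param drop_mito_ribo_genes Remove flagged mito/ribo gene rows.
#' @param min_units Detection threshold used by the gene-based rules.
#' @return list with elements `matrix` (filtered [CountMatrix]) and `audit`
#'   (list of per-rule audit records).
#' @export
filter_cells <- function(m, min_detected_genes = 100, min_total_umi = 100,
                         max_mito_pct = NULL, drop_mito_ribo_genes = FALSE,
                         min_units = 3) {
  validate_count_matrix(m)
  stopifnot(min_detected_genes >= 0, min_total_umi >= 0)
  needs_flags <- !is.null(max_mito_pct) || drop_mito_ribo_genes
  if (needs_flags && is.null(m$gene_flags)) {
    stop("gene flags missing: run annotate_genes() before mito-based filtering",
         call. = FALSE)
  }
  qc <- if (!is.null(max_mito_pct)) mito_ribo_umi(m, min_units)
        else genes_umi(m, min_units)
  audit <- list()
  removed <- character(0)
  fail_rule <- function(bad_ids, rule, params) {
    new <- setdiff(bad_ids, removed)
    audit[[length(audit) + 1L]] <<- .audit_record(rule, new, params)
    removed <<- c(removed, new)
  }
  if (min_detected_genes > 0) {
    fail_rule(qc$cell_id[qc$detected_genes < min_detected_genes],
              "min_detected_genes",
              list(min_detected_genes = min_detected_genes,
                   min_units = min_units))
  }
  if (min_total_umi > 0) {
    fail_rule(qc$cell_id[qc$total_umi < min_total_umi],
              "min_total_umi", list(min_total_umi = min_total_umi))
  }
  if (!is.null(max_mito_pct)) {
    bad <- qc$cell_id[!is.na(qc$mito_gene_pct) &
                        qc$mito_gene_pct > max_mito_pct]
    fail_rule(bad, "max_mito_pct",
              list(max_mito_pct = max_mito_pct, min_units = min_units))
  }
  keep_cells <- setdiff(m$cell_ids, removed)
  if (length(keep_cells) == 0L) {
    stop("filtering rules would remove every cell", call. = FALSE)
  }
  out <- m[, keep_cells]
  if (drop_mito_ribo_genes) {
    drop <- m$gene_flags$is_mito | m$gene_flags$is_ribo
    audit[[length(audit) + 1L]] <-
      .audit_record("drop_mito_ribo_genes", m$gene_ids[drop],
                    list(), what = "gene")
    out <- out[!drop, ]
  }
  list(matrix = out, audit = audit)
}

# Gini coefficient of a non-negative vector (zeros included); 1 by
# convention for an all-zero cell, which is maximally uninformative.
.gini <- function(x) {
  n <- length(x)
  s <- sum(x)
  if (s == 0) return(1)
  x <- sort(x)
  2 * sum(seq_len(n) * x) / (n * s) - (n + 1) / n
}

#' Lorenz-curve outlier filter for low-complexity cells
#'
#' Scores each cell by the Gini coefficient of its gene-count vector (the
#' area statistic of the Lorenz curve of cumulative count share over
#' cumulative gene share). Cells whose count mass is concentrated on very
#' few genes — the expression profile expected when most reads come from
#' background — have Gini values that are extreme relative to the rest of
#' the population. Outliers are called by a robust z-score
#' (median/MAD, one-sided towards high inequality), normal tail p-values and
#' Benjamini-Hochberg adjustment; cells with adjusted p below `alpha` are
#' removed. This realizes the estimate-background-then-discard contract of
#' Lorenz-statistic cell filtering as a documented reconstruction; it is not
#' a numerical reproduction of any external implementation.
#'
#' @param m A [CountMatrix] with at least 20 cells.
#' @param alpha BH-adjusted significance level; `alpha = 0` removes nothing.
#' @return list with `matrix` (filtered [CountMatrix]) and `audit` (an audit
#'   record whose parameters include the per-cell scores and p-values).
#' @export
lorenz_filter <- function(m, alpha = 0.05) {
  validate_count_matrix(m)
  n <- ncol(m$counts)
  if (n < 20L) {
    stop("lorenz_filter needs at least 20 cells (got ", n, ")", call. = FALSE)
  }
  dense <- as.matrix(m$counts)
  g <- apply(dense, 2, .gini)
  med <- stats::median(g)
  s <- stats::mad(g)
  if (s == 0) {
    z <- ifelse(g > med, Inf, 0)
  } else {
    z <- (g - med) / s
  }
  p <- stats::pnorm(z, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  bad <- m$cell_ids[padj < alpha]
  keep <- setdiff(m$cell_ids, bad)
  if (length(keep) == 0L) stop("lorenz_filter would remove every cell",
                               call. = FALSE)
  scores <- data.frame(cell_id = m$cell_ids, gini = g, z = z,
                       p_value = p, fdr = padj)
  list(matrix = m[, keep],
       audit = .audit_record("lorenz", bad,
                             list(alpha = alpha, scores = scores)))
}
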
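# QC and stability plots (ggplot2, Suggests). Each returns the plot object;
# callers decide where to save it.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("package 'ggplot2' is required for plotting", call. = FALSE)
  }
}

#' Detected genes vs total UMI scatter
#'
#' @param qc Output of [genes_umi()] or [mito_ribo_umi()].
#' @return A ggplot object.
#' @export
plot_genes_umi <- function(qc) {
  .need_ggplot()
  ggplot2::ggplot(qc, ggplot2::aes(x = total_umi,
                                   y = detected_genes)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total UMI", y = "detected genes")
}

#' Mitochondrial vs ribosomal gene percentage scatter
#'
#' Cells colored by detected-gene count; cells with no detected genes are
#' dropped (their percentages are undefined).
#'
#' @param qc Output of [mito_ribo_umi()].
#' @return A ggplot object.
#' @export
plot_mito_ribo <- function(qc) {
  .need_ggplot()
  qc <- qc[!is.na(qc$mito_gene_pct), , drop = FALSE]
  ggplot2::ggplot(qc, ggplot2::aes(x = ribo_gene_pct,
                                   y = mito_gene_pct,
                                   colour = detected_genes)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::labs(x = "% ribosomal of detected genes",
                  y = "% mitochondrial of detected genes",
                  colour = "detected genes")
}

#' Violin plot of CSS (and silhouette) across k
#'
#' @param violin_table Output of [violin_export()].
#' @param metric Which metric to show (`"css"` or `"silhouette"`).
#' @return A ggplot object.
#' @export
plot_stability_violin <- function(violin_table, metric = "css") {
  .need_ggplot()
  sub <- violin_table[violin_table$metric == metric, , drop = FALSE]
  ggplot2::ggplot(sub, ggplot2::aes(x = factor(k), y = value)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::labs(x = "number of clusters k", y = metric)
}
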
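#' Construct a CountMatrix
#'
#' A `CountMatrix` is the package's container for a UMI count table: a sparse
#' non-negative integer matrix of genes (rows) by cells (columns), with unique
#' gene identifiers, unique cell barcodes, optional per-gene display symbols
#' and optional mitochondrial/ribosomal flags.
#'
#' @param counts A genes-by-cells matrix (dense or [Matrix::sparseMatrix])
#'   of non-negative integer counts.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param cell_ids Character vector of unique cell barcodes (column names).
#' @param gene_symbols Optional character vector of per-gene display names.
#' @param gene_flags Optional data.frame with logical columns `is_mito` and
#'   `is_ribo`, one row per gene.
#'
#' @return An object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts),
                        gene_symbols = NULL, gene_flags = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "dMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set as dimnames of counts)",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  dimnames(counts) <- list(gene_ids, cell_ids)
  m <- structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         gene_symbols = gene_symbols, gene_flags = gene_flags),
    class = "CountMatrix"
  )
  validate_count_matrix(m)
}

#' Validate CountMatrix invariants
#'
#' Checks non-negativity and integrality of counts, dimension agreement and
#' uniqueness of gene/cell identifiers. Called by every constructor and
#' reader; exported so pipelines can re-assert after external manipulation.
#'
#' @param m A `CountMatrix`.
#' @return `m`, invisibly unchanged, or an error.
#' @export
validate_count_matrix <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  x <- m$counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(m$gene_ids) != nrow(m$counts) ||
      length(m$cell_ids) != ncol(m$counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(m$gene_ids)) {
    stop("duplicated gene identifiers: ",
         paste(unique(m$gene_ids[duplicated(m$gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$cell_ids)) {
    stop("duplicated cell barcodes: ",
         paste(unique(m$cell_ids[duplicated(m$cell_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(m$gene_symbols) && length(m$gene_symbols) != nrow(m$counts)) {
    stop("gene_symbols length does not match gene count", call. = FALSE)
  }
  if (!is.null(m$gene_flags)) {
    stopifnot(is.data.frame(m$gene_flags),
              all(c("is_mito", "is_ribo") %in% names(m$gene_flags)),
              nrow(m$gene_flags) == nrow(m$counts))
  }
  invisible(m)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%d nonzero entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (!is.null(x$gene_flags)) {
    cat(sprintf("  flagged genes: %d mito, %d ribo\n",
                sum(x$gene_flags$is_mito), sum(x$gene_flags$is_ribo)))
  }
  invisible(x)
}

#' Subset a CountMatrix by genes and/or cells
#'
#' @param x A `CountMatrix`.
#' @param i Gene index (integer, logical or character).
#' @param j Cell index (integer, logical or character).
#' @param ... Ignored.
#' @return A `CountMatrix` over the selected genes and cells.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$gene_ids)
  if (is.character(j)) j <- match(j, x$cell_ids)
  CountMatrix(x$counts[i, j, drop = FALSE],
              gene_ids = x$gene_ids[i], cell_ids = x$cell_ids[j],
              gene_symbols = if (!is.null(x$gene_symbols)) x$gene_symbols[i],
              gene_flags = if (!is.null(x$gene_flags))
                x$gene_flags[i, , drop = FALSE])
}

.first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a count matrix from disk
#'
#' Reads either a 10x-style Matrix Market directory (`matrix.mtx[.gz]` plus
#' `features.tsv[.gz]`/`genes.tsv[.gz]` and `barcodes.tsv[.gz]`, 1-based
#' triplet coordinates) or a dense CSV/TSV with gene-identifier rows and
#' barcode columns.
#'
#' @param path Directory (for `mtx_dir`) or file (for `csv`/`tsv`).
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param transpose For CSV/TSV input laid out as cells x genes, set `TRUE`.
#' @return A [CountMatrix].
#' @export
load_counts <- function(path, format = c("mtx_dir", "csv", "tsv"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input not found: ", path, call. = FALSE)
  }
  if (format == "mtx_dir") {
    mtx <- .first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
    feat <- .first_existing(path, c("features.tsv", "features.tsv.gz",
                                    "genes.tsv", "genes.tsv.gz"))
    bc <- .first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    for (need in list(list("matrix.mtx", mtx),
                      list("features.tsv/genes.tsv", feat),
                      list("barcodes.tsv", bc))) {
      if (is.null(need[[2]])) {
        stop("missing file in MTX directory: ", need[[1]], call. = FALSE)
      }
    }
    counts <- Matrix::readMM(mtx)
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(features) != nrow(counts) || length(barcodes) != ncol(counts)) {
      stop("feature/barcode files do not match matrix dimensions",
           call. = FALSE)
    }
    symbols <- if (ncol(features) >= 2) features[[2]] else NULL
    CountMatrix(counts, gene_ids = features[[1]], cell_ids = barcodes,
                gene_symbols = symbols)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    mat <- as.matrix(tab)
    if (transpose) mat <- t(mat)
    if (!is.numeric(mat)) stop("non-numeric entries in count table",
                               call. = FALSE)
    CountMatrix(mat, gene_ids = rownames(mat), cell_ids = colnames(mat))
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [load_counts()]: writes either a 10x-style MTX directory or a
#' dense CSV/TSV. Round-trips are lossless for integer counts and for gene
#' and cell ordering.
#'
#' @param m A [CountMatrix].
#' @param path Output directory (`mtx_dir`) or file (`csv`/`tsv`).
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
save_counts <- function(m, path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  validate_count_matrix(m)
  if (ncol(m$counts) == 0L || nrow(m$counts) == 0L) {
    stop("refusing to write a degenerate matrix with zero genes or cells",
         call. = FALSE)
  }
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
    symbols <- if (is.null(m$gene_symbols)) m$gene_ids else m$gene_symbols
    utils::write.table(
      data.frame(m$gene_ids, symbols, "Gene Expression"),
      file.path(path, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    dense <- as.matrix(m$counts)
    tab <- data.frame(gene = m$gene_ids, dense, check.names = FALSE)
    colnames(tab) <- c("gene", m$cell_ids)
    ok <- tryCatch({
      utils::write.table(tab, path, sep = sep, quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", path, call. = FALSE)
  }
  invisible(path)
}
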
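# Gene annotation: ENSEMBL id -> symbol mapping and mito/ribo flagging.
# Flagging rule (community convention): mitochondrial genes carry the "MT-"
# (human) / "mt-" (mouse) symbol prefix; cytosolic ribosomal protein genes
# match ^RP[SL]<digit> case-insensitively (Rps*/Rpl* families).
# Mitochondrial ribosomal proteins (Mrps*/Mrpl*) are excluded by default and
# can be opted in with include_mrp = TRUE.

.is_mito_symbol <- function(symbols) grepl("^mt-", symbols, ignore.case = TRUE)

.is_ribo_symbol <- function(symbols, include_mrp = FALSE) {
  hit <- grepl("^rp[sl][0-9]", symbols, ignore.case = TRUE)
  if (include_mrp) {
    hit <- hit | grepl("^mrp[sl][0-9]", symbols, ignore.case = TRUE)
  }
  hit
}

.strip_ensembl_version <- function(ids) sub("\\.[0-9]+$", "", ids)

.read_gtf_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("package 'rtracklayer' is required to read GTF annotation",
         call. = FALSE)
  }
  # cheap structural pre-scan so malformed lines are reported by number
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(body)[which(nfield < 9L)[1]]
    stop(sprintf("malformed GTF line %d in %s: expected >= 9 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (!"gene_id" %in% names(meta)) {
    stop("GTF has no gene_id attribute: ", path, call. = FALSE)
  }
  if ("type" %in% names(meta) && any(meta$type == "gene")) {
    meta <- meta[meta$type == "gene", , drop = FALSE]
  }
  symbol <- if ("gene_name" %in% names(meta)) meta$gene_name else meta$gene_id
  symbol[is.na(symbol) | !nzchar(symbol)] <-
    meta$gene_id[is.na(symbol) | !nzchar(symbol)]
  ann <- data.frame(ensembl_id = meta$gene_id, symbol = symbol,
                    chromosome = as.character(meta$seqnames),
                    stringsAsFactors = FALSE)
  ann[!duplicated(ann$ensembl_id), , drop = FALSE]
}

#' Annotate genes with symbols and mitochondrial/ribosomal flags
#'
#' Maps ENSEMBL gene identifiers to display symbols using a GTF file (Ensembl
#' dialect) or an annotation data.frame with columns `ensembl_id` and
#' `symbol`, then sets per-gene `is_mito`/`is_ribo` flags from the symbols.
#' Counts, dimensions and ordering are never modified. Version suffixes
#' (`".N"`) on the matrix gene identifiers are stripped before matching;
#' unmapped genes keep their identifier as symbol. Symbols duplicated after
#' mapping are disambiguated by appending `":<ensembl_id>"`. With
#' `annotation = NULL` no mapping is attempted and flags are (re)derived from
#' the current symbols (or identifiers).
#'
#' @param m A [CountMatrix] whose `gene_ids` are ENSEMBL IDs (or already
#'   symbols when `annotation = NULL`).
#' @param annotation Path to a GTF file, or a data.frame with `ensembl_id`
#'   and `symbol` columns, or `NULL`.
#' @param include_mrp Count mitochondrial ribosomal proteins (Mrps*/Mrpl*) as
#'   ribosomal. Default `FALSE` (cytosolic families only).
#' @return `m` with `gene_symbols` and `gene_flags` filled in.
#' @export
annotate_genes <- function(m, annotation, include_mrp = FALSE) {
  validate_count_matrix(m)
  if (is.null(annotation)) {
    symbols <- if (is.null(m$gene_symbols)) m$gene_ids else m$gene_symbols
  } else {
    if (is.character(annotation) && length(annotation) == 1L) {
      if (!file.exists(annotation)) {
        stop("annotation file not found: ", annotation, call. = FALSE)
      }
      annotation <- .read_gtf_annotation(annotation)
    }
    stopifnot(is.data.frame(annotation),
              all(c("ensembl_id", "symbol") %in% names(annotation)))
    key <- .strip_ensembl_version(m$gene_ids)
    idx <- match(key, .strip_ensembl_version(annotation$ensembl_id))
    symbols <- ifelse(is.na(idx), m$gene_ids, annotation$symbol[idx])
    if (all(is.na(idx))) {
      warning("no gene identifiers were mapped by the annotation",
              call. = FALSE)
    }
    dup <- duplicated(symbols) | duplicated(symbols, fromLast = TRUE)
    symbols[dup] <- paste0(symbols[dup], ":", m$gene_ids[dup])
  }
  m$gene_symbols <- symbols
  m$gene_flags <- data.frame(
    is_mito = .is_mito_symbol(symbols),
    is_ribo = .is_ribo_symbol(symbols, include_mrp = include_mrp)
  )
  # a gene cannot be both; mito prefix wins (flag sets stay disjoint)
  m$gene_flags$is_ribo <- m$gene_flags$is_ribo & !m$gene_flags$is_mito
  validate_count_matrix(m)
  m
}
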
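# Shared fixtures and independent brute-force oracles.

# small CountMatrix from a dense matrix with auto ids
toy_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL,
                       symbols = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("c%d", seq_len(ncol(counts)))
  CountMatrix(counts, gene_ids = gene_ids, cell_ids = cell_ids,
              gene_symbols = symbols)
}

# construct a perturbation-run object directly from labels (bypassing the
# clusterer), for oracle tests of the scoring stage
fake_run <- function(cell_ids, labels, index = 1L) {
  structure(list(run_index = index, seed = index,
                 retained_cell_ids = cell_ids,
                 partition = partition(cell_ids, labels)),
            class = "PermutationRun")
}

# the 6-cell worked example: reference {a,b,c},{d,e,f}; one run retains
# {a,b,c,d,e} and clusters it as {a,b},{c,d,e}
six_cell_example <- function() {
  ref <- partition(letters[1:6], c(1, 1, 1, 2, 2, 2))
  run <- fake_run(c("a", "b", "c", "d", "e"), c(1, 1, 2, 2, 2))
  list(reference = ref, run = run)
}

# brute-force CSS from raw set operations, independent of the table-based
# implementation path
css_oracle <- function(reference, runs) {
  cells <- reference$cell_ids
  ref_sets <- split(cells, reference$labels)
  vapply(cells, function(i) {
    js <- c()
    for (run in runs) {
      ret <- run$partition$cell_ids
      if (!i %in% ret) next
      ref_cl <- ref_sets[[which(vapply(ref_sets, function(s) i %in% s,
                                       logical(1)))]]
      A <- intersect(ref_cl, ret)
      run_sets <- split(ret, run$partition$labels)
      B <- run_sets[[which(vapply(run_sets, function(s) i %in% s,
                                  logical(1)))]]
      js <- c(js, length(intersect(A, B)) / length(union(A, B)))
    }
    if (length(js)) mean(js) else NA_real_
  }, numeric(1))
}

# brute-force Hennig clusterwise stability from raw set operations
hennig_oracle <- function(reference, runs) {
  ref_sets <- split(reference$cell_ids, reference$labels)
  vapply(seq_along(ref_sets), function(r) {
    g <- c()
    for (run in runs) {
      ret <- run$partition$cell_ids
      C <- intersect(ref_sets[[r]], ret)
      if (length(C) == 0L) next
      run_sets <- split(ret, run$partition$labels)
      g <- c(g, max(vapply(run_sets, function(D) {
        length(intersect(C, D)) / length(union(C, D))
      }, numeric(1))))
    }
    if (length(g)) mean(g) else NA_real_
  }, numeric(1))
}

# Gini oracle via the mean-absolute-difference identity, independent of the
# sorted-cumulative formula used in the implementation
gini_oracle <- function(x) {
  n <- length(x)
  if (sum(x) == 0) return(1)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
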
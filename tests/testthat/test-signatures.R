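test_that("cpm matches its closed form and normalizes columns", {
  m <- toy_matrix(cbind(c(5, 995), c(1, 3)))
  x <- cpm(m)
  expect_equal(x[1, 1], 5e6 / 1000)
  expect_equal(unname(colSums(x)), c(1e6, 1e6))
  expect_equal(x[1, 2], 2.5e5)
  zero <- toy_matrix(cbind(c(1, 1), c(0, 0)))
  expect_error(cpm(zero), "c2")
})

test_that("anova_like agrees with stats::oneway.test gene by gene", {
  set.seed(41)
  m <- toy_matrix(matrix(rnbinom(30 * 24, mu = 20, size = 5), 30, 24))
  part <- partition(m$cell_ids, rep(1:3, each = 8))
  res <- anova_like(m, part)
  Y <- log2(cpm(m) + 1)
  for (g in c(1, 7, 13, 22, 30)) {
    ow <- oneway.test(Y[g, ] ~ factor(part$labels), var.equal = TRUE)
    expect_equal(res$statistic[g], unname(ow$statistic), tolerance = 1e-8)
    expect_equal(res$p_value[g], ow$p.value, tolerance = 1e-8)
  }
})

test_that("anova_like handles constants, order/relabel invariance, BH", {
  set.seed(43)
  counts <- matrix(rnbinom(40 * 18, mu = 10, size = 5), 40, 18)
  counts[5, ] <- 10                      # same count everywhere
  csum <- colSums(counts)
  counts <- rbind(counts, max(csum) + 10 - csum)  # equalize depths
  m <- toy_matrix(counts)
  part <- partition(m$cell_ids, rep(1:3, each = 6))
  res <- anova_like(m, part)
  # equal depth + equal count -> identical log2 CPM -> F = 0, p = 1
  expect_equal(res$statistic[5], 0)
  expect_equal(res$p_value[5], 1)
  # fdr >= p always, and BH is monotone along the p-ordering
  ok <- res$tested
  expect_true(all(res$fdr[ok] >= res$p_value[ok] - 1e-12))
  o <- order(res$p_value[ok])
  expect_true(all(diff(cummin(rev(res$fdr[ok][o]))) <= 1e-12))

  # invariance to cell order and cluster relabeling
  perm <- sample(ncol(counts))
  m2 <- m[, perm]
  part2 <- partition(m2$cell_ids, c(3, 1, 2)[part$labels[perm]])
  res2 <- anova_like(m2, part2)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-10)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-10)

  # validation
  expect_error(anova_like(m, partition(m$cell_ids, rep(1, 18))), "2 clusters")
  expect_error(anova_like(m, partition(m$cell_ids, c(1, rep(2, 17)))),
               ">= 2 cells")
})

test_that("planted markers reach small FDR in their planted cluster", {
  sim <- generate_synthetic(synthetic_presets("easy3"))
  part <- partition(names(sim$truth$labels), sim$truth$labels)
  res <- anova_like(sim$matrix, part)
  for (cl in seq_along(sim$truth$marker_genes)) {
    rows <- res[match(sim$truth$marker_genes[[cl]], res$gene_id), ]
    expect_true(all(rows$fdr < 0.01))
    expect_true(mean(rows$best_cluster == cl) > 0.95)
  }
})

test_that("pure-null genes keep the type-I error near nominal", {
  set.seed(47)
  counts <- matrix(rnbinom(500 * 60, mu = rlnorm(500, 2, 1), size = 10),
                   500, 60)
  m <- toy_matrix(counts)
  part <- partition(m$cell_ids, rep(1:3, each = 20))
  res <- anova_like(m, part)
  frac <- mean(res$p_value[res$tested] < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
  # FDR control: few null genes pass fdr < 0.05
  expect_lte(mean(res$fdr[res$tested] < 0.05), 0.02)
})

test_that("top_markers ranks, caps and thresholds deterministically", {
  res <- data.frame(gene_id = sprintf("g%d", 1:6),
                    tested = TRUE,
                    statistic = c(50, 40, 30, 20, 10, 5),
                    p_value = c(1e-8, 1e-6, 1e-6, 0.01, 0.2, 0.6),
                    fdr = c(1e-7, 3e-6, 3e-6, 0.02, 0.3, 0.7),
                    best_cluster = c(1, 1, 1, 2, 2, 1))
  mk <- top_markers(res, fdr_threshold = 0.05)
  expect_equal(mk$cluster_1, c("g1", "g2", "g3"))   # fdr tie -> statistic
  expect_equal(mk$cluster_2, "g4")
  expect_equal(top_markers(res, per_cluster_n = 2)$cluster_1, c("g1", "g2"))
  expect_true(all(lengths(top_markers(res, fdr_threshold = 0)) == 0))
})

test_that("heatmap_export orders cells by cluster and standardizes safely", {
  set.seed(53)
  counts <- matrix(rpois(8 * 12, 6) + 1, 8, 12)
  counts[3, ] <- 0                        # all-zero gene
  m <- toy_matrix(counts)
  labels <- rep(c(2, 1), 6)               # interleaved on purpose
  part <- partition(m$cell_ids, labels)
  hm <- heatmap_export(m, part, c("g1", "g3", "g5"))
  # cells grouped contiguously by cluster
  cl <- part$labels[match(hm$cell_order, part$cell_ids)]
  expect_true(all(diff(cl) >= 0))
  # zero-variance row standardized to zeros, no NaN anywhere
  expect_true(all(hm$matrix["g3", ] == 0))
  expect_false(any(is.nan(hm$matrix)))
  expect_equal(sort(rownames(hm$matrix)), c("g1", "g3", "g5"))
  # per-gene cell tables carry cluster and CPM
  expect_equal(names(hm$cell_tables), c("g1", "g3", "g5"))
  expect_equal(nrow(hm$cell_tables$g1), 12)
  expect_error(heatmap_export(m, part, "nope"), "nope")
})

test_that("planted marker genes dominate their cluster in CPM", {
  sim <- generate_synthetic(synthetic_presets("easy3"))
  part <- partition(names(sim$truth$labels), sim$truth$labels)
  markers <- vapply(sim$truth$marker_genes, `[`, character(1), 1)
  hm <- heatmap_export(sim$matrix, part, unname(markers))
  for (cl in seq_along(markers)) {
    tab <- hm$cell_tables[[markers[[cl]]]]
    means <- tapply(tab$cpm, tab$cluster, mean)
    expect_equal(unname(which.max(means)), cl)
  }
})
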
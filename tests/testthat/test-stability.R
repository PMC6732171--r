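test_that("CSS matches the hand-computed 6-cell worked example exactly", {
  ex <- six_cell_example()
  css <- cell_stability_score(ex$reference, list(ex$run))
  got <- setNames(css$css, css$cell_id)
  expect_identical(got[["a"]], 2 / 3)   # {a,b} vs {a,b,c}
  expect_identical(got[["b"]], 2 / 3)
  expect_identical(got[["c"]], 1 / 5)   # {c} overlap, union {a,b,c,d,e}
  expect_identical(got[["d"]], 2 / 3)   # {d,e} vs {c,d,e}
  expect_identical(got[["e"]], 2 / 3)
  expect_true(is.na(got[["f"]]))        # never retained
  expect_equal(css$n_retained, c(1L, 1L, 1L, 1L, 1L, 0L))
  # and agrees with the raw set-operation oracle
  expect_equal(unname(got[1:5]), unname(css_oracle(ex$reference,
                                                   list(ex$run))[1:5]))
})

test_that("Hennig cluster stability follows its max-Jaccard definition", {
  ex <- six_cell_example()
  st <- cluster_stability(ex$reference, list(ex$run))
  # cluster {a,b,c}: best match {a,b} -> 2/3; cluster {d,e,f}: {c,d,e} -> 2/3
  expect_equal(st$stability, c(2 / 3, 2 / 3))
  expect_equal(st$stability, unname(hennig_oracle(ex$reference,
                                                  list(ex$run))))
  # a cluster dissolved into singletons scores 1 / |C ∩ retained|
  ref <- partition(letters[1:4], c(1, 1, 1, 2))
  run <- fake_run(letters[1:4], 1:4)
  st2 <- cluster_stability(ref, list(run))
  expect_equal(st2$stability[1], 1 / 3)
})

test_that("perfect reproduction gives CSS = 1 and stability = 1", {
  ref <- partition(sprintf("c%d", 1:9), rep(1:3, each = 3))
  runs <- lapply(1:4, function(b) {
    keep <- setdiff(1:9, b)             # drop one cell per run
    fake_run(sprintf("c%d", keep), rep(1:3, each = 3)[keep], b)
  })
  css <- cell_stability_score(ref, runs)
  expect_true(all(css$css == 1))
  expect_true(all(cluster_stability(ref, runs)$stability == 1))
})

test_that("singleton shattering gives the 1/|C| closed form", {
  ref <- partition(c("a", "b", "c"), c(1, 1, 1))
  run <- fake_run(c("a", "b", "c"), 1:3)
  css <- cell_stability_score(ref, list(run))
  expect_equal(css$css, rep(1 / 3, 3))
})

test_that("implementation equals the brute-force oracle on random cases", {
  set.seed(19)
  for (case in 1:25) {
    n <- sample(4:8, 1)
    cells <- sprintf("c%d", seq_len(n))
    ref <- partition(cells, sample(1:3, n, replace = TRUE))
    runs <- lapply(seq_len(sample(1:3, 1)), function(b) {
      keep <- sort(sample(n, sample(2:n, 1)))
      fake_run(cells[keep], sample(1:3, length(keep), replace = TRUE), b)
    })
    css <- cell_stability_score(ref, runs)
    expect_equal(setNames(css$css, css$cell_id), css_oracle(ref, runs),
                 tolerance = 1e-14)
    st <- cluster_stability(ref, runs)
    expect_equal(st$stability, unname(hennig_oracle(ref, runs)),
                 tolerance = 1e-14)
    # defined CSS is always in (0, 1]
    ok <- !is.na(css$css)
    expect_true(all(css$css[ok] > 0 & css$css[ok] <= 1))
  }
})

test_that("CSS depends only on co-membership, not label values", {
  set.seed(23)
  cells <- sprintf("c%d", 1:12)
  ref <- partition(cells, rep(1:3, each = 4))
  runs <- lapply(1:3, function(b) {
    keep <- sort(sample(12, 10))
    fake_run(cells[keep], sample(1:3, 10, replace = TRUE), b)
  })
  base <- cell_stability_score(ref, runs)$css
  # relabel reference clusters 1,2,3 -> 3,1,2 and run clusters by +1 mod 3
  ref2 <- partition(cells, c(3, 1, 2)[rep(1:3, each = 4)])
  runs2 <- lapply(runs, function(r) {
    fake_run(r$partition$cell_ids, (r$partition$labels %% 3) + 1,
             r$run_index)
  })
  expect_equal(cell_stability_score(ref2, runs2)$css, base)
})

test_that("label noise degrades mean CSS monotonically", {
  set.seed(31)
  n <- 60
  cells <- sprintf("c%d", seq_len(n))
  ref_labels <- rep(1:3, each = 20)
  ref <- partition(cells, ref_labels)
  mean_css_at <- function(q) {
    runs <- lapply(1:20, function(b) {
      lab <- ref_labels
      flip <- sample(n, round(q * n))
      lab[flip] <- sample(1:3, length(flip), replace = TRUE)
      fake_run(cells, lab, b)
    })
    mean(cell_stability_score(ref, runs)$css)
  }
  m0 <- mean_css_at(0)
  m2 <- mean_css_at(0.2)
  m5 <- mean_css_at(0.5)
  expect_equal(m0, 1)
  expect_true(m0 >= m2 && m2 >= m5)
})

test_that("permutation runs have exact sizes, seeds and reproducibility", {
  sim <- generate_synthetic(synthetic_presets("easy2"))
  m <- sim$matrix
  spec <- clusterer_spec("kmeans_log", k = 2)
  runs <- permute_and_cluster(m, spec, B = 5, f = 0.1, master_seed = 7)
  expect_length(runs, 5)
  for (b in seq_along(runs)) {
    expect_length(runs[[b]]$retained_cell_ids, 90)   # n=100, f=0.1
    expect_equal(runs[[b]]$seed, 7L + b)
    expect_true(all(runs[[b]]$retained_cell_ids %in% m$cell_ids))
  }
  runs2 <- permute_and_cluster(m, spec, B = 5, f = 0.1, master_seed = 7)
  expect_identical(lapply(runs, `[[`, "retained_cell_ids"),
                   lapply(runs2, `[[`, "retained_cell_ids"))
  expect_identical(lapply(runs, function(r) r$partition$labels),
                   lapply(runs2, function(r) r$partition$labels))
  # f small enough that floor(f*n) = 0 retains everything
  runs0 <- permute_and_cluster(m, spec, B = 2, f = 0.005, master_seed = 1)
  expect_length(runs0[[1]]$retained_cell_ids, 100)
  expect_error(permute_and_cluster(m, spec, B = 2, f = 1.2), "between 0 and 1")
  expect_error(permute_and_cluster(m, spec, B = 2, f = 0.99), "minimum")
})

test_that("run_stability is reproducible bit-for-bit from the master seed", {
  sim <- generate_synthetic(synthetic_presets("easy2"))
  spec <- clusterer_spec("kmeans_log", k = 2)
  r1 <- run_stability(sim$matrix, spec, B = 8, f = 0.1, master_seed = 5)
  r2 <- run_stability(sim$matrix, spec, B = 8, f = 0.1, master_seed = 5)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$cluster_stability, r2$cluster_stability)
  expect_identical(r1$reference$labels, r2$reference$labels)
})

test_that("violin_export emits long rows for defined values only", {
  sim <- generate_synthetic(synthetic_presets("easy2"))
  spec <- clusterer_spec("kmeans_log", k = 2)
  rep1 <- run_stability(sim$matrix, spec, B = 5, f = 0.1, master_seed = 2)
  tab <- violin_export(rep1)
  n_def <- sum(!is.na(rep1$scores$css))
  expect_equal(sum(tab$metric == "css"), n_def)
  expect_true(all(tab$value[tab$metric == "css"] > 0))
  expect_true(all(tab$k == 2))
  # empty input keeps the header contract
  empty <- violin_export(list())
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("cell_id", "metric", "value", "k"))
})

test_that("stability artifacts round-trip through save_stability_report", {
  sim <- generate_synthetic(synthetic_presets("easy2"))
  spec <- clusterer_spec("kmeans_log", k = 2)
  rep1 <- run_stability(sim$matrix, spec, B = 4, f = 0.1, master_seed = 2)
  d <- tempfile()
  save_stability_report(rep1, d)
  expect_true(all(file.exists(file.path(d,
    c("reference_labels.csv", "cell_scores.csv", "cluster_stability.csv",
      "violin_table.csv", "params.json")))))
  scores <- read.csv(file.path(d, "cell_scores.csv"))
  expect_equal(scores$css, rep1$scores$css)
  params <- jsonlite::read_json(file.path(d, "params.json"))
  expect_equal(params$B, 4)
  expect_equal(params$f, 0.1)
})
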
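test_that("qc_filter_cells applies the documented rules and boundaries", {
  counts <- matrix(100, 10, 6)
  x <- tiny_expression(counts)  # umi_total = 1000 per cell
  res <- qc_filter_cells(x)
  expect_equal(res$report$retained, 6)
  expect_equal(res$report$min_umi + res$report$max_umi +
                 res$report$mito + res$report$doublet, 0)

  # boundary: 499 < 500 fails, 500 passes
  counts2 <- counts
  counts2[, 1] <- c(499, rep(0, 9))
  counts2[, 2] <- c(500, rep(0, 9))
  x2 <- tiny_expression(counts2)
  res2 <- qc_filter_cells(x2)
  expect_equal(res2$report$min_umi, 1)
  expect_equal(res2$report$retained, 5)

  # first-failing-rule attribution: a cell failing umi AND mito counts as umi
  x3 <- tiny_expression(counts2, mito = c(0.5, rep(0, 5)))
  res3 <- qc_filter_cells(x3)
  expect_equal(res3$report$min_umi, 1)
  expect_equal(res3$report$mito, 0)

  x4 <- tiny_expression(counts)
  x4$metadata$mito_fraction <- NULL
  expect_error(qc_filter_cells(x4), "mito_fraction",
               class = "ifnregnet_input_error")
})

test_that("qc survivors equal brute-force per-cell rule evaluation", {
  sim <- simulate_expression(simulation_config(
    n_genes = 300, n_cells = 500, qc_fail_fraction = 0.1, seed = 9))
  p <- qc_params()
  res <- qc_filter_cells(sim$matrix, p)
  md <- sim$matrix$metadata
  keep <- logical(nrow(md))
  for (i in seq_len(nrow(md)))  # independent per-cell predicate loop
    keep[i] <- md$umi_total[i] >= p$min_umi && md$umi_total[i] <= p$max_umi &&
      md$mito_fraction[i] <= p$max_mito_fraction &&
      md$doublet_score[i] <= p$max_doublet_score
  expect_equal(res$report$retained, sum(keep))
  expect_identical(colnames(res$matrix$counts),
                   colnames(sim$matrix$counts)[keep])
})

test_that("qc_filter_nuclei applies snATAC thresholds", {
  nuc <- data.frame(frip = c(0.5, 0.10, 0.5, 0.5),
                    fragments = c(5e4, 5e4, 2e4, 2e6))
  res <- qc_filter_nuclei(nuc)
  expect_equal(res$report, list(frip = 1, min_fragments = 1,
                                max_fragments = 1, retained = 1))
})

test_that("normalize_log matches its closed form and preserves zeros", {
  x <- tiny_expression(matrix(c(9, 1, 0, 5), 2, 2))
  norm <- normalize_log(x, scale = 10)
  expect_equal(norm[, 1], c(g1 = log(10), g2 = log(2)))
  expect_equal(norm[1, 2], 0)
  # brute-force recomputation on a random 5x4 matrix
  set.seed(1)
  m <- matrix(rpois(20, 4) + 1, 5, 4)
  xx <- tiny_expression(m)
  nn <- as.matrix(normalize_log(xx, scale = 100))
  ref <- log1p(sweep(m, 2, colSums(m), "/") * 100)
  expect_equal(unname(nn), unname(ref), tolerance = 1e-12)
  zero <- tiny_expression(matrix(0, 2, 2))
  expect_error(normalize_log(zero), class = "ifnregnet_input_error")
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ifnregnet_input_error")
  set.seed(42)
  p <- runif(100)
  adj <- bh_adjust(p)
  m <- length(p)
  r <- rank(p, ties.method = "min")
  brute <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / r[p >= p[i]]))
  }, 0)
  expect_equal(adj, brute, tolerance = 1e-12)
  expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("find_markers filters, tests and reports per spec", {
  set.seed(3)
  m <- matrix(rpois(30 * 20, 5), 30, 20)
  m[1, ] <- c(rpois(10, 40), rpois(10, 2))  # strong marker
  m[2, ] <- 0                               # never expressed
  x <- tiny_expression(m)
  norm <- normalize_log(x)
  de <- find_markers(norm, 1:10, 11:20)
  expect_false(de$tested[2])
  expect_equal(de$p_value[2], 1)
  expect_true(de$tested[1])
  expect_lt(de$adjusted_p[1], 0.01)
  expect_true(all(de$adjusted_p >= de$p_value - 1e-12))
  expect_true(all(de$pct_group1 >= 0 & de$pct_group1 <= 1))

  # identical groups: logFC 0, p 1
  m2 <- matrix(rep(c(5, 1), each = 10), 2, 10, byrow = TRUE)
  de2 <- find_markers(normalize_log(tiny_expression(m2)), 1:5, 6:10,
                      logfc_threshold = 0)
  expect_equal(de2$log2_fold_change, c(0, 0))
  expect_equal(de2$p_value, c(1, 1))

  expect_error(find_markers(norm, 1:2, 3:20),
               class = "ifnregnet_input_error")
  expect_error(find_markers(norm, 1:10, 10:20),
               class = "ifnregnet_input_error")
})

test_that("normal-approximation Wilcoxon matches the exact permutation
           oracle at n = 10 per group", {
  set.seed(8)
  v <- c(rnorm(10, 1), rnorm(10, 0))
  x <- tiny_expression(matrix(round(exp(v) * 10), 1, 20))
  norm <- normalize_log(x)
  de <- find_markers(norm, 1:10, 11:20, min_pct = 0, logfc_threshold = 0)

  vals <- as.numeric(norm[1, ])
  r <- rank(vals)
  obs <- sum(r[1:10])
  combs <- combn(20, 10)  # exhaustive permutation null of the rank sum
  null <- colSums(matrix(r[combs], nrow = 10))
  p_exact <- mean(abs(null - sum(r) * 10 / 20) >= abs(obs - sum(r) * 10 / 20))
  expect_lt(abs(de$p_value[1] - p_exact) / p_exact, 0.10)
})

test_that("find_markers is invariant to gene and cell order", {
  set.seed(5)
  m <- matrix(rpois(40 * 30, 3), 40, 30)
  x <- tiny_expression(m)
  norm <- normalize_log(x)
  de <- find_markers(norm, 1:15, 16:30, min_pct = 0, logfc_threshold = 0)
  gperm <- sample(40)
  de_p <- find_markers(norm[gperm, ], 1:15, 16:30, min_pct = 0,
                       logfc_threshold = 0)
  expect_equal(de_p$p_value[order(de_p$gene_id)],
               de$p_value[order(de$gene_id)])
  cperm <- c(sample(1:15), sample(16:30))
  de_c <- find_markers(norm[, cperm], colnames(norm)[1:15],
                       colnames(norm)[16:30], min_pct = 0,
                       logfc_threshold = 0)
  expect_equal(de_c$p_value, de$p_value)
})

test_that("composition_test statistics and errors match the contract", {
  meta <- data.frame(
    cluster = rep(c("k1", "k2"), each = 50),
    condition = rep(c("a", "b"), 50))
  res <- composition_test(meta, n_perm = 200, seed = 1)
  expect_equal(res$log2_fold_difference, c(0, 0))
  expect_true(all(res$permutation_p > 0 & res$permutation_p <= 1))

  # closed form: 8% vs 2% -> log2FD -> 2 as eps -> 0 (large n)
  n <- 20000
  meta2 <- data.frame(
    cluster = c(rep("hot", 0.08 * n), rep("cold", 0.92 * n),
                rep("hot", 0.02 * n), rep("cold", 0.98 * n)),
    condition = rep(c("a", "b"), each = n))
  res2 <- composition_test(meta2, n_perm = 10, seed = 1)
  expect_equal(res2$log2_fold_difference[res2$cluster == "hot"], 2,
               tolerance = 0.01)

  expect_error(
    composition_test(data.frame(cluster = "k", condition = c("a", "b", "c"))),
    "condition levels", class = "ifnregnet_input_error")
})
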
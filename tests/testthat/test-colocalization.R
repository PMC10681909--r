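test_that("aggregate_families sums member motifs exactly", {
  counts <- matrix(c(1, 3, 2, 4, 5, 0), 1, 6,
                   dimnames = list("p1", sprintf("m%d", 1:6)))
  fam <- setNames(c("A", "A", "B", "B", "C", "C"), sprintf("m%d", 1:6))
  out <- aggregate_families(counts, fam)
  expect_equal(out["p1", ], c(A = 4, B = 6, C = 5))

  # identity when one family per motif
  fam1 <- setNames(sprintf("F%d", 1:6), sprintf("m%d", 1:6))
  expect_equal(unname(aggregate_families(counts, fam1)[1, order(c(1:6))]),
               unname(counts[1, ]))

  expect_error(aggregate_families(counts, fam[1:3]), "m4",
               class = "ifnregnet_input_error")

  # random instance equals a loop-based oracle
  set.seed(4)
  rc <- matrix(rpois(300, 2), 30, 10,
               dimnames = list(sprintf("p%d", 1:30), sprintf("m%d", 1:10)))
  rf <- setNames(sample(c("X", "Y", "Z"), 10, TRUE), colnames(rc))
  agg <- aggregate_families(rc, rf)
  for (f in unique(rf)) for (p in rownames(rc))
    expect_equal(agg[p, f], sum(rc[p, names(rf)[rf == f]]))
})

test_that("correlation_network computes Pearson r and drops degenerates", {
  set.seed(9)
  a <- rpois(50, 3)
  counts <- cbind(A = a, B = 2L * a, C = rpois(50, 3), D = 0L)
  rownames(counts) <- sprintf("p%d", 1:50)
  expect_warning(net <- correlation_network(counts), "D")
  expect_equal(net$weights["A", "B"], 1)
  expect_true(all(is.na(diag(net$weights))))
  expect_equal(net$weights, t(net$weights))
  expect_false("D" %in% net$nodes)

  # definitional recomputation within 1e-12
  set.seed(10)
  rc <- matrix(rpois(2000, 4), 200, 10,
               dimnames = list(sprintf("p%d", 1:200), sprintf("F%d", 1:10)))
  net2 <- correlation_network(rc)
  for (i in 1:9) for (j in (i + 1):10) {
    x <- rc[, i]; y <- rc[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(net2$weights[i, j], r, tolerance = 1e-12)
  }
  expect_error(correlation_network(rc, peak_subset = "nope"),
               class = "ifnregnet_input_error")
})

make_network <- function(w) {
  diag(w) <- NA
  structure(list(nodes = rownames(w), weights = w, dropped = character(0)),
            class = "family_network")
}

test_that("spectral_communities separates cliques, keeps uniform graphs whole", {
  nodes <- sprintf("F%d", 1:6)
  w <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  w[1:3, 1:3] <- 0.9; w[4:6, 4:6] <- 0.9
  part <- spectral_communities(make_network(w))
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:3])), 1)
  expect_equal(length(unique(part$membership[4:6])), 1)
  expect_gt(part$modularity, 0)

  u <- matrix(0.5, 6, 6, dimnames = list(nodes, nodes))
  part_u <- spectral_communities(make_network(u))
  expect_equal(length(unique(part_u$membership)), 1)
})

test_that("an isolated node becomes exactly one extra singleton", {
  nodes <- sprintf("F%d", 1:7)
  w <- matrix(0, 7, 7, dimnames = list(nodes, nodes))
  w[1:3, 1:3] <- 0.9; w[4:6, 4:6] <- 0.9  # F7 isolated
  part <- spectral_communities(make_network(w))
  expect_equal(length(unique(part$membership)), 3)
  expect_equal(sum(part$membership == part$membership["F7"]), 1)
})

test_that("returned modularity beats the trivial partition and matches igraph", {
  skip_if_not_installed("igraph")
  set.seed(30)
  n <- 10
  nodes <- sprintf("F%d", 1:n)
  w <- matrix(runif(n * n, 0, 0.3), n, n, dimnames = list(nodes, nodes))
  w <- (w + t(w)) / 2
  w[1:5, 1:5] <- w[1:5, 1:5] + 0.6
  w[6:10, 6:10] <- w[6:10, 6:10] + 0.6
  part <- spectral_communities(make_network(w))
  expect_gte(part$modularity, 0)

  a <- w; diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::cluster_leading_eigen(g)
  expect_equal(part$modularity,
               igraph::modularity(g, igraph::membership(ref),
                                  weights = igraph::E(g)$weight),
               tolerance = 0.05)
  expect_equal(adjusted_rand(part$membership,
                             igraph::membership(ref)[nodes]), 1)
})

test_that("adjusted_rand closed form and compare_partitions", {
  p_same <- structure(list(membership = setNames(c(1, 1, 2, 2),
                                                 sprintf("n%d", 1:4)),
                           modularity = 0), class = "partition")
  expect_equal(compare_partitions(p_same, p_same)$adjusted_rand, 1)

  singletons <- structure(list(membership = setNames(1:4,
                                                     sprintf("n%d", 1:4)),
                               modularity = 0), class = "partition")
  together <- structure(list(membership = setNames(rep(1, 4),
                                                   sprintf("n%d", 1:4)),
                             modularity = 0), class = "partition")
  expect_equal(compare_partitions(singletons, together)$adjusted_rand, 0)

  # random partitions match the contingency-table closed form
  set.seed(44)
  for (k in 1:20) {
    l1 <- sample(1:3, 12, TRUE); l2 <- sample(1:4, 12, TRUE)
    tab <- table(l1, l2)
    nij <- sum(choose(tab, 2)); a <- sum(choose(rowSums(tab), 2))
    b <- sum(choose(colSums(tab), 2)); n2 <- choose(12, 2)
    exp_ari <- (nij - a * b / n2) / ((a + b) / 2 - a * b / n2)
    if (is.finite(exp_ari))
      expect_equal(adjusted_rand(l1, l2), exp_ari, tolerance = 1e-12)
  }

  pairs <- cbind(c("n1", "n1"), c("n2", "n3"))
  res <- compare_partitions(p_same, singletons, pairs = pairs)
  expect_equal(res$pair_overlap$co_community_1, c(TRUE, FALSE))
  expect_equal(res$pair_overlap$co_community_2, c(FALSE, FALSE))
  expect_error(compare_partitions(p_same, structure(
    list(membership = setNames(1:3, c("a", "b", "c"))), class = "partition")),
    class = "ifnregnet_input_error")
})

test_that("network is invariant to peak order", {
  set.seed(3)
  rc <- matrix(rpois(400, 3), 40, 10,
               dimnames = list(sprintf("p%d", 1:40), sprintf("F%d", 1:10)))
  n1 <- correlation_network(rc)
  n2 <- correlation_network(rc[sample(40), ])
  expect_equal(n1$weights, n2$weights, tolerance = 1e-12)
})
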
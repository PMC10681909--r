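#' Aggregate motif hit counts to TF-family counts
#'
#' @param hits A `motif_hit_matrix` or a bare peaks x motifs count matrix.
#' @param family_map Named character vector `motif_id -> family`.
#' @return Peaks x families integer matrix (column = sum over member
#'   motifs).
#' @export
aggregate_families <- function(hits, family_map) {
  counts <- if (inherits(hits, "motif_hit_matrix")) hits$counts else hits
  unmapped <- setdiff(colnames(counts), names(family_map))
  if (length(unmapped))
    abort_input(sprintf("motif(s) without a family: %s",
                        paste(unmapped, collapse = ", ")))
  fam <- family_map[colnames(counts)]
  fams <- sort(unique(unname(fam)))
  ind <- outer(fam, fams, "==") + 0
  out <- counts %*% ind
  colnames(out) <- fams
  out
}

#' TF-family motif co-occurrence network
#'
#' Pearson correlation between every pair of families' motif counts across
#' the chosen peaks. Families with fewer than `min_nonzero` nonzero counts
#' or zero variance on the subset are dropped with a warning; their edges
#' are absent.
#'
#' @param counts Peaks x families count matrix (see
#'   [aggregate_families()]).
#' @param peak_subset Peak ids to correlate over (default: all rows).
#' @param min_nonzero Minimum nonzero counts per retained family.
#' @return A `family_network`: list with `nodes`, `weights` (symmetric
#'   correlation matrix, `NA` diagonal) and `dropped`.
#' @export
correlation_network <- function(counts, peak_subset = NULL,
                                min_nonzero = 5L) {
  if (is.null(peak_subset)) peak_subset <- rownames(counts)
  rows <- intersect(peak_subset, rownames(counts))
  if (!length(rows))
    abort_input("peak subset has no peaks in common with the count matrix")
  if (length(rows) < 3) abort_input("need at least 3 peaks")
  sub <- counts[rows, , drop = FALSE]
  nz <- colSums(sub > 0)
  v <- apply(sub, 2, var)
  keep <- nz >= min_nonzero & v > 0
  if (any(!keep))
    warning(sprintf("family(ies) dropped (low count or zero variance): %s",
                    paste(colnames(sub)[!keep], collapse = ", ")))
  w <- matrix(NA_real_, sum(keep), sum(keep),
              dimnames = list(colnames(sub)[keep], colnames(sub)[keep]))
  if (sum(keep) >= 2) {
    w <- cor(sub[, keep, drop = FALSE])
    diag(w) <- NA_real_
  }
  structure(list(nodes = colnames(sub)[keep], weights = w,
                 dropped = colnames(sub)[!keep]),
            class = "family_network")
}

# modularity of a partition of a weighted undirected graph (adjacency a,
# zero diagonal): Q = sum_c (e_c - a_c^2)
modularity_value <- function(a, membership) {
  m2 <- sum(a)
  if (m2 == 0) return(0)
  q <- 0
  for (comm in unique(membership)) {
    idx <- membership == comm
    q <- q + sum(a[idx, idx]) / m2 - (sum(a[idx, ]) / m2)^2
  }
  q
}

# leading eigenvector with deterministic sign: largest-magnitude entry > 0
leading_eigen <- function(b) {
  e <- eigen(b, symmetric = TRUE)
  v <- e$vectors[, 1]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  list(value = e$values[1], vector = v)
}

#' Spectral community detection (leading eigenvector)
#'
#' Removes edges with weight `<= weight_floor` (negative correlations are
#' dropped by the default floor of 0, as modularity is undefined for
#' negative weights), then partitions the remaining weighted graph by
#' Newman's leading-eigenvector method: recursive bisection on the sign of
#' the leading eigenvector of the (generalized) modularity matrix, stopping
#' when no split increases modularity. Deterministic: the eigenvector sign
#' is fixed by making its largest-magnitude entry positive.
#'
#' @param net A `family_network`.
#' @param weight_floor Edges at or below this weight are removed.
#' @return A `partition`: list with `membership` (named integer vector) and
#'   `modularity`.
#' @export
spectral_communities <- function(net, weight_floor = 0) {
  nodes <- net$nodes
  if (length(nodes) < 2) abort_input("need at least 2 retained nodes")
  a <- net$weights
  a[is.na(a)] <- 0
  a[a <= weight_floor] <- 0
  diag(a) <- 0
  if (sum(a) == 0) {
    warning("graph empty after edge filtering; every node is a singleton")
    return(structure(list(membership = setNames(seq_along(nodes), nodes),
                          modularity = 0), class = "partition"))
  }
  deg <- rowSums(a)
  m2 <- sum(a)
  b_full <- a - outer(deg, deg) / m2

  # zero-degree nodes cannot affect modularity: fixed as singletons so that
  # adding an isolated node adds exactly one singleton community
  isolated <- which(deg == 0)
  membership <- setNames(rep(1L, length(nodes)), nodes)
  if (length(isolated))
    membership[isolated] <- seq_along(isolated) + 1L
  next_id <- max(membership) + 1L
  queue <- list(setdiff(seq_along(nodes), isolated))
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    bg <- b_full[g, g, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)  # generalized modularity matrix
    le <- leading_eigen(bg)
    if (le$value <= 1e-12) next
    s <- ifelse(le$vector >= 0, 1, -1)
    if (all(s == s[1])) next
    dq <- as.numeric(t(s) %*% bg %*% s) / (2 * m2)
    if (dq <= 1e-12) next
    g1 <- g[s > 0]; g2 <- g[s < 0]
    membership[g2] <- next_id
    next_id <- next_id + 1L
    queue <- c(queue, list(g1), list(g2))
  }
  membership <- setNames(match(membership, unique(membership)), nodes)
  structure(list(membership = membership,
                 modularity = modularity_value(a, membership)),
            class = "partition")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement via the contingency-table closed form.
#'
#' @param l1,l2 Label vectors over the same items.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand <- function(l1, l2) {
  if (length(l1) != length(l2)) abort_input("labelings differ in length")
  tab <- table(l1, l2)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(l1))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Compare two partitions of the same node set
#'
#' Reports, for designated node pairs, whether they share a community in
#' each partition, plus the adjusted Rand index between the partitions.
#'
#' @param p1,p2 `partition` objects over the same nodes.
#' @param pairs Optional 2-column matrix / data.frame of node pairs.
#' @return List: `adjusted_rand` and (if `pairs` given) data.frame
#'   `pair_overlap` with `co_community_1`, `co_community_2` flags.
#' @export
compare_partitions <- function(p1, p2, pairs = NULL) {
  n1 <- names(p1$membership); n2 <- names(p2$membership)
  if (!setequal(n1, n2))
    abort_input("partitions cover different node sets")
  m2 <- p2$membership[n1]
  out <- list(adjusted_rand = adjusted_rand(p1$membership, m2))
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    if (!all(pairs %in% n1)) abort_input("pair node(s) not in partitions")
    out$pair_overlap <- data.frame(
      node_a = pairs[, 1], node_b = pairs[, 2],
      co_community_1 = p1$membership[pairs[, 1]] ==
        p1$membership[pairs[, 2]],
      co_community_2 = m2[pairs[, 1]] == m2[pairs[, 2]],
      row.names = NULL)
  }
  out
}
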
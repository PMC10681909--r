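#' Cluster-composition permutation test between two conditions
#'
#' For each cluster, compares its proportion between the two conditions with
#' `log2_fold_difference = log2((prop1 + eps) / (prop2 + eps))`, where
#' `eps = 1 / total cells`. The null distribution is built by shuffling
#' condition labels over cells; the two-sided p-value is
#' `(1 + #{|perm stat| >= |obs stat|}) / (1 + n_perm)`.
#'
#' @param meta Per-cell metadata data.frame.
#' @param cluster_col,condition_col Column names in `meta`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @return data.frame: `cluster`, `proportion_condition1`,
#'   `proportion_condition2`, `log2_fold_difference`, `permutation_p`,
#'   `n_permutations`.
#' @export
composition_test <- function(meta, cluster_col = "cluster",
                             condition_col = "condition",
                             n_perm = 10000L, seed = 1L) {
  for (col in c(cluster_col, condition_col))
    if (is.null(meta[[col]])) abort_input(sprintf("column '%s' missing", col))
  cond <- as.character(meta[[condition_col]])
  clus <- as.character(meta[[cluster_col]])
  if (anyNA(cond) || anyNA(clus))
    abort_input("every cell must carry cluster and condition labels")
  levels_cond <- sort(unique(cond))
  if (length(levels_cond) != 2L)
    abort_input(sprintf("exactly 2 condition levels required, got %d",
                        length(levels_cond)))
  clusters <- sort(unique(clus))
  empty <- vapply(clusters, function(cl) sum(clus == cl) == 0, TRUE)
  if (any(empty)) {
    warning(sprintf("cluster(s) absent in both conditions skipped: %s",
                    paste(clusters[empty], collapse = ", ")))
    clusters <- clusters[!empty]
  }
  n <- length(cond)
  eps <- 1 / n
  ci <- match(clus, clusters)
  is1 <- cond == levels_cond[1]
  n1 <- sum(is1); n2 <- n - n1
  k <- length(clusters)

  stat_of <- function(sel1) {
    p1 <- tabulate(ci[sel1], k) / max(n1, 1L)
    p2 <- tabulate(ci[!sel1], k) / max(n2, 1L)
    log2((p1 + eps) / (p2 + eps))
  }
  obs <- stat_of(is1)
  exceed <- integer(k)
  with_seed(derive_seed(seed, "composition"), {
    for (b in seq_len(n_perm)) {
      sel <- logical(n)
      sel[sample.int(n, n1)] <- TRUE
      exceed <- exceed + (abs(stat_of(sel)) >= abs(obs))
    }
  })
  p1_obs <- tabulate(ci[is1], k) / max(n1, 1L)
  p2_obs <- tabulate(ci[!is1], k) / max(n2, 1L)
  data.frame(cluster = clusters,
             proportion_condition1 = p1_obs,
             proportion_condition2 = p2_obs,
             log2_fold_difference = obs,
             permutation_p = (1 + exceed) / (1 + n_perm),
             n_permutations = n_perm, row.names = NULL)
}
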
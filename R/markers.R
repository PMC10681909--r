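#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped at 1 and monotone in rank.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    abort_input("p-values must lie in [0,1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

# two-sided Wilcoxon rank-sum, normal approximation with tie correction,
# vectorized over the rows of a dense matrix (cells of group 1 first)
wilcox_rows <- function(mat, n1) {
  n2 <- ncol(mat) - n1
  n <- n1 + n2
  res <- matrix(NA_real_, nrow(mat), 2,
                dimnames = list(rownames(mat), c("W", "p")))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    r <- rank(v)
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    t <- tabulate(match(v, unique(v)))
    tie <- sum(t^3 - t)
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    if (sig2 <= 0) {
      res[i, ] <- c(w, 1)
    } else {
      z <- (w - n1 * n2 / 2) / sqrt(sig2)
      res[i, ] <- c(w, min(1, 2 * pnorm(-abs(z))))
    }
  }
  res
}

#' Wilcoxon marker detection between two cell groups
#'
#' Genes expressed in at least `min_pct` of either group and with
#' `|log2 fold change| >= logfc_threshold` are tested by a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction);
#' remaining genes are reported untested with `p_value = 1`. Adjusted
#' p-values are Benjamini-Hochberg over the full gene universe (untested
#' genes enter with p = 1), so the correction is not weakened by the
#' effect-size pre-filter.
#' `log2_fold_change = log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))`
#' on the normalized values.
#'
#' @param norm Normalized genes x cells matrix (see [normalize_log()]).
#' @param group1,group2 Disjoint cell-id (or column index) vectors, each
#'   with at least 3 cells.
#' @param min_pct Minimum expressed fraction in either group.
#' @param logfc_threshold Minimum absolute log2 fold change.
#' @return data.frame: `gene_id`, `log2_fold_change`, `pct_group1`,
#'   `pct_group2`, `p_value`, `adjusted_p`, `tested`.
#' @export
find_markers <- function(norm, group1, group2, min_pct = 0.01,
                         logfc_threshold = 0.25) {
  if (!length(group1) || !length(group2))
    abort_input("both groups must be nonempty")
  if (is.character(group1)) group1 <- match(group1, colnames(norm))
  if (is.character(group2)) group2 <- match(group2, colnames(norm))
  if (anyNA(group1) || anyNA(group2))
    abort_input("group contains unknown cell id(s)")
  if (length(intersect(group1, group2)))
    abort_input("groups must be disjoint")
  if (length(group1) < 3 || length(group2) < 3)
    abort_input("each group needs at least 3 cells")

  m1 <- as.matrix(norm[, group1, drop = FALSE])
  m2 <- as.matrix(norm[, group2, drop = FALSE])
  pct1 <- rowMeans(m1 > 0)
  pct2 <- rowMeans(m2 > 0)
  lfc <- log2((rowMeans(expm1(m1)) + 1) / (rowMeans(expm1(m2)) + 1))
  tested <- (pct1 >= min_pct | pct2 >= min_pct) &
    abs(lfc) >= logfc_threshold

  p <- rep(1, nrow(norm))
  if (any(tested)) {
    wt <- wilcox_rows(cbind(m1, m2)[tested, , drop = FALSE], ncol(m1))
    p[tested] <- wt[, "p"]
  }
  # correction spans the whole gene universe (untested genes carry p = 1),
  # as the adjusted p-values of the reference single-cell toolkit do;
  # adjusting only the post-logFC-filter survivors would not control the
  # false-discovery proportion (selection on observed effect size)
  adj <- bh_adjust(p)
  data.frame(gene_id = rownames(norm), log2_fold_change = lfc,
             pct_group1 = pct1, pct_group2 = pct2,
             p_value = p, adjusted_p = adj,
             tested = tested, row.names = NULL)
}
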
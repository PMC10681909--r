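#' Gene-set module score with expression-matched background
#'
#' Scores a gene set (e.g. a 96-gene ISG panel) per cell as the mean
#' normalized expression of the set genes minus the mean of a randomly drawn
#' background pool of `pool_factor` genes per set gene, sampled from the
#' same equal-frequency mean-expression bin. The background pool is thus
#' `pool_factor` times the size of the input set; duplicates across set
#' genes are allowed so that factor is exact.
#'
#' @param norm Normalized genes x cells matrix (see [normalize_log()]).
#' @param genes Character vector of set gene ids (at least half must be
#'   present in the matrix; absentees are dropped with a warning).
#' @param n_bins Number of equal-frequency bins on mean expression.
#' @param pool_factor Background genes drawn per set gene.
#' @param seed Integer seed for background sampling.
#' @param set_name Label recorded in the provenance.
#' @return A `score_vector`: data.frame (`cell_id`, `raw`, `z`) with
#'   attribute `provenance` (gene set, parameters, seed, background ids).
#' @export
module_score <- function(norm, genes, n_bins = 24L, pool_factor = 10L,
                         seed = 1L, set_name = "gene_set") {
  if (n_bins < 2) abort_input("n_bins must be at least 2")
  present <- intersect(genes, rownames(norm))
  if (!length(present))
    abort_input("gene set has no genes in common with the matrix")
  if (length(present) < length(genes)) {
    if (length(present) < 0.5 * length(genes))
      abort_input(sprintf(
        "only %d of %d gene-set genes present (need at least half)",
        length(present), length(genes)))
    warning(sprintf("%d gene-set gene(s) absent from matrix, dropped",
                    length(genes) - length(present)))
  }
  gene_means <- Matrix::rowMeans(norm)
  # canonical order (mean, then id) so scores do not depend on gene order
  ord <- order(gene_means, rownames(norm))
  bins <- integer(nrow(norm))
  bins[ord] <- as.integer(ceiling(seq_len(nrow(norm)) / nrow(norm) * n_bins))
  names(bins) <- rownames(norm)

  background <- character(0)
  with_seed(derive_seed(seed, paste0("module_score:", set_name)), {
    for (g in present) {
      cand <- sort(setdiff(names(bins)[bins == bins[[g]]], genes))
      if (length(cand) >= pool_factor) {
        draw <- cand[sample.int(length(cand), pool_factor)]
      } else if (length(cand)) {
        warning(sprintf(
          "bin of gene '%s' has %d candidates (< pool_factor); sampling with replacement",
          g, length(cand)))
        draw <- cand[sample.int(length(cand), pool_factor, replace = TRUE)]
      } else {
        warning(sprintf("bin of gene '%s' empty of background candidates", g))
        next
      }
      background <- c(background, draw)
    }
  })
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  bg_mean <- if (length(background))
    Matrix::colMeans(norm[background, , drop = FALSE]) else 0
  raw <- set_mean - bg_mean
  out <- data.frame(cell_id = colnames(norm), raw = as.numeric(raw),
                    z = NA_real_, row.names = NULL)
  attr(out, "provenance") <- list(
    set_name = set_name, genes = present, n_bins = n_bins,
    pool_factor = pool_factor, seed = seed, background = background)
  class(out) <- c("score_vector", "data.frame")
  zscore(out)
}

#' Z-transform module scores
#'
#' `z = (raw - mean) / SD` with the population SD; a zero-SD score vector
#' yields all-zero z with a warning.
#'
#' @param scores A `score_vector` (or data.frame with a `raw` column).
#' @return The input with its `z` column (re)computed.
#' @export
zscore <- function(scores) {
  raw <- scores$raw
  if (length(raw) < 2) abort_input("need at least 2 cells to z-score")
  s <- sqrt(mean((raw - mean(raw))^2))
  if (s == 0) {
    warning("constant raw scores; z set to 0")
    scores$z <- rep(0, length(raw))
  } else {
    scores$z <- (raw - mean(raw)) / s
  }
  scores
}

#' Compare module scores between two cell groups
#'
#' Unpaired mode (default) runs a two-sided Wilcoxon rank-sum test; paired
#' mode runs the signed-rank test on matched pairs (groups must align).
#'
#' @param scores A `score_vector`.
#' @param group1,group2 Disjoint cell-id vectors (unpaired mode needs at
#'   least 3 cells each).
#' @param paired Use the signed-rank test on matched pairs.
#' @param value Which column to compare, `"z"` (default) or `"raw"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_scores <- function(scores, group1, group2, paired = FALSE,
                           value = c("z", "raw")) {
  value <- match.arg(value)
  v <- setNames(scores[[value]], scores$cell_id)
  if (anyNA(match(c(group1, group2), scores$cell_id)))
    abort_input("group contains unknown cell id(s)")
  if (length(intersect(group1, group2)))
    abort_input("groups must be disjoint")
  if (paired) {
    if (length(group1) != length(group2))
      abort_input("paired mode needs equally sized, aligned groups")
    ht <- wilcox.test(v[group1], v[group2], paired = TRUE, exact = NULL)
  } else {
    if (length(group1) < 3 || length(group2) < 3)
      abort_input("unpaired mode needs at least 3 cells per group")
    ht <- suppressWarnings(wilcox.test(v[group1], v[group2]))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
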
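#' Simulate a single-cell expression matrix with planted structure
#'
#' Draws negative-binomial counts with gene-level means drawn log-normal,
#' assigns each cell a condition and a cluster (per-condition cluster
#' proportions from the config), raises ISG-panel gene means by
#' `exp(isg_shift)` in the designated ISG-high cluster, plants `n_deg`
#' condition-DEGs at `deg_fold`, and populates per-cell `mito_fraction` and
#' `doublet_score` columns with a `qc_fail_fraction` of cells above the QC
#' cutoffs.
#'
#' @param config A [simulation_config()].
#' @return A list with `matrix` (an `expression_matrix`) and `truth`
#'   (ground-truth ids: `isg_gene_ids`, `isg_high_cluster`, `deg_gene_ids`,
#'   `deg_direction`, `enriched_clusters`).
#' @export
simulate_expression <- function(config) {
  config <- validate_config(config)
  with_seed(derive_seed(config$seed, "expression"), {
    ng <- config$n_genes; nc <- config$n_cells
    genes <- sprintf("gene_%d", seq_len(ng))
    cells <- sprintf("cell_%d", seq_len(nc))
    clusters <- sprintf("cluster_%d", seq_len(config$n_clusters))
    conds <- names(config$cluster_proportions_by_condition)

    # cells split evenly over conditions, clusters drawn per condition
    condition <- rep(conds, length.out = nc)
    cluster <- character(nc)
    for (cond in conds) {
      idx <- which(condition == cond)
      cluster[idx] <- sample(clusters, length(idx), replace = TRUE,
                             prob = config$cluster_proportions_by_condition[[cond]])
    }

    # gene relative abundances: log-normal, normalized to a simplex
    rel <- exp(rnorm(ng, 0, 1))
    rel <- rel / sum(rel)
    depth <- config$depth_mean * exp(rnorm(nc, 0, 0.3))

    # curated panels and reported DEGs concern detectably expressed genes:
    # plant them above the 30th abundance percentile
    eligible <- genes[rel >= quantile(rel, 0.3)]
    if (config$isg_panel_size > length(eligible))
      abort_config(
        "config field 'isg_panel_size' exceeds the expressed-gene pool (70% of n_genes)")
    isg_gene_ids <- sample(eligible, config$isg_panel_size)
    isg_high_cluster <- clusters[1]
    if (config$n_deg > length(setdiff(eligible, isg_gene_ids)))
      abort_config(
        "config field 'n_deg' exceeds the expressed-gene pool left after the ISG panel")
    deg_gene_ids <- sample(setdiff(eligible, isg_gene_ids), config$n_deg)
    deg_up <- rep(c(TRUE, FALSE), length.out = length(deg_gene_ids))

    # per-cell mean vector = rel * depth, modulated by planted effects
    mu <- outer(rel, depth)
    rownames(mu) <- genes
    if (config$isg_shift != 0) {
      in_high <- cluster == isg_high_cluster
      mu[isg_gene_ids, in_high] <- mu[isg_gene_ids, in_high] *
        exp(config$isg_shift)
    }
    if (config$deg_fold != 1 && length(deg_gene_ids)) {
      in_c1 <- condition == conds[1]
      mu[deg_gene_ids[deg_up], in_c1] <-
        mu[deg_gene_ids[deg_up], in_c1] * config$deg_fold
      mu[deg_gene_ids[!deg_up], !in_c1] <-
        mu[deg_gene_ids[!deg_up], !in_c1] * config$deg_fold
    }

    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                     nrow = ng, dimnames = list(genes, cells))

    # QC covariates: mostly below cutoffs, a planted fraction above
    fail <- runif(nc) < config$qc_fail_fraction
    fail_rule <- ifelse(runif(nc) < 0.5, "mito", "doublet")
    mito <- runif(nc, 0, 0.004)
    doublet <- runif(nc, 0, 0.002)
    mito[fail & fail_rule == "mito"] <-
      runif(sum(fail & fail_rule == "mito"), 0.006, 0.05)
    doublet[fail & fail_rule == "doublet"] <-
      runif(sum(fail & fail_rule == "doublet"), 0.003, 0.02)

    md <- data.frame(condition = condition, cluster = cluster,
                     mito_fraction = mito, doublet_score = doublet,
                     row.names = cells)
    enriched <- character(0)
    if (length(conds) >= 2) {
      p1 <- config$cluster_proportions_by_condition[[1]]
      p2 <- config$cluster_proportions_by_condition[[2]]
      enriched <- clusters[abs(log2((p1 + 1e-12) / (p2 + 1e-12))) >= 1]
    }
    list(
      matrix = expression_matrix(Matrix::Matrix(counts, sparse = TRUE), md),
      truth = list(
        isg_gene_ids = isg_gene_ids,
        isg_high_cluster = isg_high_cluster,
        deg_gene_ids = deg_gene_ids,
        deg_direction = setNames(ifelse(deg_up, "cond1_up", "cond2_up"),
                                 deg_gene_ids),
        enriched_clusters = enriched,
        config = unclass(config)))
  })
}
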
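#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_expression()] and [simulate_regulatory()]. Defaults describe a
#' desk-scale heart-injury-like experiment: two conditions, a handful of
#' endothelial-like clusters of which one carries an elevated
#' interferon-stimulated-gene (ISG) program, planted condition DEGs, and a
#' small genome whose "IFN-EC gene" set carries elevated motif density and
#' accessibility.
#'
#' @param n_genes Number of genes in the expression matrix.
#' @param n_cells Number of cells.
#' @param n_clusters Number of cell clusters.
#' @param isg_panel_size Size of the ISG panel (default 96, the size of the
#'   ISG scoring panel used throughout).
#' @param isg_shift Natural-log effect added to ISG gene means in the
#'   ISG-high cluster (0 disables planting).
#' @param n_deg Number of planted condition-DEGs.
#' @param deg_fold Linear fold change of planted DEGs between conditions.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param depth_mean Expected UMI per cell.
#' @param cluster_proportions_by_condition Named list (one element per
#'   condition) of per-cluster proportion vectors, each summing to 1. The
#'   default plants a 8% vs 2% shift (log2 fold difference 2) in the last
#'   cluster.
#' @param qc_fail_fraction Fraction of cells planted above the mito/doublet
#'   QC cutoffs.
#' @param genome_n_seqs,seq_len Number and length (bp) of genome sequences.
#' @param n_motifs,motif_len Number of PWMs and their length (bp).
#' @param n_families Number of TF families the motifs are divided into.
#' @param n_family_blocks Number of co-occurrence blocks families are
#'   grouped into (motifs of families in one block are co-planted).
#' @param co_plant_prob Probability each family of the chosen block
#'   contributes a motif at a planting event.
#' @param plant_rate Expected planted motif occurrences per non-target peak
#'   (target peaks receive `plant_rate * target_density_multiplier`).
#' @param target_density_multiplier Planting-rate ratio for peaks of target
#'   genes vs background genes.
#' @param n_target_genes Number of designated "IFN-EC" target genes.
#' @param access_multiplier Accessibility fold for target-gene peaks in the
#'   designated population.
#' @param seed Global integer seed; stage substreams derive from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_genes = 2000L, n_cells = 2000L, n_clusters = 5L,
    isg_panel_size = 96L, isg_shift = 0.5,
    n_deg = 100L, deg_fold = 2,
    dispersion = 0.5, depth_mean = 5000,
    cluster_proportions_by_condition = NULL,
    qc_fail_fraction = 0.05,
    genome_n_seqs = 4L, seq_len = 50000L,
    n_motifs = 8L, motif_len = 8L,
    n_families = 4L, n_family_blocks = 2L,
    co_plant_prob = 0.9, plant_rate = 1.0,
    target_density_multiplier = 3,
    n_target_genes = 15L,
    access_multiplier = 2,
    seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_clusters = as.integer(n_clusters),
    isg_panel_size = as.integer(isg_panel_size), isg_shift = isg_shift,
    n_deg = as.integer(n_deg), deg_fold = deg_fold,
    dispersion = dispersion, depth_mean = depth_mean,
    cluster_proportions_by_condition = cluster_proportions_by_condition,
    qc_fail_fraction = qc_fail_fraction,
    genome_n_seqs = as.integer(genome_n_seqs), seq_len = as.integer(seq_len),
    n_motifs = as.integer(n_motifs), motif_len = as.integer(motif_len),
    n_families = as.integer(n_families),
    n_family_blocks = as.integer(n_family_blocks),
    co_plant_prob = co_plant_prob, plant_rate = plant_rate,
    target_density_multiplier = target_density_multiplier,
    n_target_genes = as.integer(n_target_genes),
    access_multiplier = access_multiplier,
    seed = as.integer(seed),
    rng = "Mersenne-Twister")
  if (is.null(cfg$cluster_proportions_by_condition)) {
    k <- cfg$n_clusters
    base <- rep(1 / k, k)
    p1 <- base; p2 <- base
    if (k >= 2) {
      # plant an 8% vs 2% shift in the last cluster (log2 fold difference 2)
      p1[k] <- 0.08; p2[k] <- 0.02
      p1[seq_len(k - 1)] <- (1 - p1[k]) / (k - 1)
      p2[seq_len(k - 1)] <- (1 - p2[k]) / (k - 1)
    }
    cfg$cluster_proportions_by_condition <- list(cond1 = p1, cond2 = p2)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("n_genes", "n_cells", "n_clusters", "isg_panel_size",
           "genome_n_seqs", "seq_len", "n_motifs", "motif_len",
           "n_families", "n_family_blocks", "depth_mean")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      abort_config(sprintf("config field '%s' must be a positive count", f))
  for (f in c("n_deg", "n_target_genes", "qc_fail_fraction", "dispersion",
              "plant_rate"))
    if (cfg[[f]] < 0)
      abort_config(sprintf("config field '%s' must be nonnegative", f))
  if (cfg$isg_panel_size > cfg$n_genes)
    abort_config("config field 'isg_panel_size' exceeds n_genes")
  if (cfg$n_deg > cfg$n_genes)
    abort_config("config field 'n_deg' exceeds n_genes")
  if (cfg$motif_len > cfg$seq_len)
    abort_config("config field 'motif_len' exceeds seq_len")
  if (cfg$n_family_blocks > cfg$n_families)
    abort_config("config field 'n_family_blocks' exceeds n_families")
  if (cfg$n_families > cfg$n_motifs)
    abort_config("config field 'n_families' exceeds n_motifs")
  props <- cfg$cluster_proportions_by_condition
  if (!is.list(props) || length(props) < 1L ||
      is.null(names(props)) || any(!nzchar(names(props))))
    abort_config(
      "config field 'cluster_proportions_by_condition' must be a named list")
  for (cond in names(props)) {
    p <- props[[cond]]
    if (length(p) != cfg$n_clusters)
      abort_config(sprintf(
        "config field 'cluster_proportions_by_condition$%s' needs %d entries",
        cond, cfg$n_clusters))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      abort_config(sprintf(
        "config field 'cluster_proportions_by_condition$%s' must sum to 1",
        cond))
  }
  structure(cfg, class = "simulation_config")
}
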
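#' Default pipeline configuration
#'
#' Returns the full run configuration with every stage enabled and every
#' parameter at its documented default. Override any entry via the
#' `overrides` list (recursively merged), or in a YAML/JSON file passed to
#' [run_pipeline()].
#'
#' @param out_dir Output directory for the run.
#' @param seed Global seed; per-stage substreams derive from it.
#' @param overrides Named list merged over the defaults.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir = "ifnregnet_run", seed = 1L,
                            overrides = list()) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    stages = list(simulate = TRUE, qc = TRUE, score = TRUE, markers = TRUE,
                  composition = TRUE, scan = TRUE, nms = TRUE,
                  network = TRUE),
    simulation = list(),
    qc = list(),
    score = list(n_bins = 24L, pool_factor = 10L),
    markers = list(min_pct = 0.01, logfc_threshold = 0.25),
    composition = list(n_perm = 1000L),
    scan = list(p_cutoff = 1e-4, granularity = 1000L),
    nms = list(promoter_bp = 2000L, level = "family", population = "popA"),
    network = list(min_nonzero = 5L, weight_floor = 0))
  merge_lists <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    abort_config(sprintf("unknown config field(s): %s",
                         paste(bad, collapse = ", ")))
  cfg <- merge_lists(cfg, overrides)
  structure(cfg, class = "run_config")
}

read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_config("YAML config given but the yaml package is unavailable")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(out_dir = raw$out_dir %||% "ifnregnet_run",
                  seed = raw$seed %||% 1L, overrides = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order: simulate (expression +
#' regulatory inputs) -> qc -> score (ISG module score) -> markers ->
#' composition -> scan (motif hits) -> nms -> network. A failing stage
#' stops everything downstream; the run manifest (parameters, output
#' hashes, timestamps) is written to `out_dir/manifest.json` regardless.
#'
#' @param config A `run_config` from [pipeline_config()], a plain list of
#'   overrides, or a path to a YAML/JSON config file.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    config <- pipeline_config(overrides = config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("ifnregnet")),
                   seed = config$seed, rng = "Mersenne-Twister",
                   stages = list())
  on.exit(jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE))

  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    rec <- list(params = config[[name]] %||% list(),
                started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    outputs <- tryCatch(fun(), error = function(e) {
      rec$status <<- "failed"; rec$error <<- conditionMessage(e)
      manifest$stages[[name]] <<- rec
      stop(e)
    })
    rec$status <- "ok"
    rec$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    rec$outputs <- hash_files(unlist(outputs))
    manifest$stages[[name]] <<- rec
  }

  run_stage("simulate", function() {
    sim_cfg <- do.call(simulation_config,
                       c(config$simulation, list(seed = config$seed)))
    state$expr <- simulate_expression(sim_cfg)
    state$reg <- simulate_regulatory(sim_cfg)
    d <- file.path(out_dir, "inputs")
    write_counts(state$expr$matrix, file.path(d, "expression"))
    write_regulatory_inputs(state$reg, d)
    jsonlite::write_json(state$expr$truth[c("isg_gene_ids",
                                            "isg_high_cluster",
                                            "deg_gene_ids",
                                            "enriched_clusters")],
                         file.path(d, "expression_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list.files(d, recursive = TRUE, full.names = TRUE)
  })

  run_stage("qc", function() {
    qcp <- do.call(qc_params, config$qc)
    res <- qc_filter_cells(state$expr$matrix, qcp)
    state$filtered <- res$matrix
    state$norm <- normalize_log(res$matrix)
    p <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(res$report, p, auto_unbox = TRUE, digits = NA)
    p
  })

  run_stage("score", function() {
    sc <- module_score(state$norm, state$expr$truth$isg_gene_ids,
                       n_bins = config$score$n_bins,
                       pool_factor = config$score$pool_factor,
                       seed = config$seed, set_name = "ISG")
    state$scores <- sc
    p <- file.path(out_dir, "isg_scores.tsv")
    write.table(sc, p, sep = "\t", quote = FALSE, row.names = FALSE)
    pj <- file.path(out_dir, "isg_scores_provenance.json")
    jsonlite::write_json(attr(sc, "provenance"), pj, auto_unbox = TRUE,
                         digits = NA)
    c(p, pj)
  })

  run_stage("markers", function() {
    md <- state$filtered$metadata
    conds <- sort(unique(md$condition))
    de <- find_markers(state$norm,
                       rownames(md)[md$condition == conds[1]],
                       rownames(md)[md$condition == conds[2]],
                       min_pct = config$markers$min_pct,
                       logfc_threshold = config$markers$logfc_threshold)
    state$markers <- de
    p <- file.path(out_dir, "markers.tsv")
    write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })

  run_stage("composition", function() {
    comp <- composition_test(state$filtered$metadata,
                             n_perm = config$composition$n_perm,
                             seed = config$seed)
    p <- file.path(out_dir, "composition.tsv")
    write.table(comp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })

  run_stage("scan", function() {
    state$hits <- scan_peaks(state$reg$genome, state$reg$peaks,
                             state$reg$motifs,
                             p_cutoff = config$scan$p_cutoff,
                             granularity = config$scan$granularity)
    p <- file.path(out_dir, "motif_hits.tsv")
    write.table(cbind(peak_id = rownames(state$hits$counts),
                      as.data.frame(state$hits$counts)),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })

  run_stage("nms", function() {
    assignment <- assign_peaks(state$reg$peaks, state$reg$genes,
                               promoter_bp = config$nms$promoter_bp)
    nms <- compute_nms(state$hits, state$reg$peaks, assignment,
                       state$reg$access,
                       population = config$nms$population,
                       level = config$nms$level,
                       family_map = state$reg$family_map)
    state$nms <- nms
    state$assignment <- assignment
    target <- state$reg$truth$target_gene_ids
    bg <- setdiff(rownames(nms), target)
    cmp <- lapply(colnames(nms), function(f)
      c(list(tf_or_family = f), compare_nms(nms, target, bg, f)))
    p <- file.path(out_dir, "nms.tsv")
    write.table(cbind(gene_id = rownames(nms), as.data.frame(nms)),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    pj <- file.path(out_dir, "nms_comparison.json")
    jsonlite::write_json(cmp, pj, auto_unbox = TRUE, digits = NA)
    c(p, pj)
  })

  run_stage("network", function() {
    fam_counts <- aggregate_families(state$hits, state$reg$family_map)
    target_peaks <- names(state$reg$truth$peak_gene)[
      state$reg$truth$peak_gene %in% state$reg$truth$target_gene_ids]
    net <- suppressWarnings(
      correlation_network(fam_counts, target_peaks,
                          min_nonzero = config$network$min_nonzero))
    part <- spectral_communities(net,
                                 weight_floor = config$network$weight_floor)
    edges <- which(upper.tri(net$weights), arr.ind = TRUE)
    p <- file.path(out_dir, "network_edges.tsv")
    write.table(data.frame(
      family_a = rownames(net$weights)[edges[, 1]],
      family_b = colnames(net$weights)[edges[, 2]],
      r = net$weights[edges]), p, sep = "\t", quote = FALSE,
      row.names = FALSE)
    pm <- file.path(out_dir, "communities.tsv")
    write.table(data.frame(family = names(part$membership),
                           community = part$membership),
                pm, sep = "\t", quote = FALSE, row.names = FALSE)
    pj <- file.path(out_dir, "network_summary.json")
    jsonlite::write_json(list(modularity = part$modularity,
                              n_communities = length(unique(part$membership)),
                              dropped = net$dropped),
                         pj, auto_unbox = TRUE, digits = NA)
    c(p, pm, pj)
  })

  invisible(manifest)
}

#' Packaged demo configuration
#'
#' A small configuration that runs every stage in well under a minute.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A `run_config`.
#' @export
demo_config <- function(out_dir = tempfile("ifnregnet_demo_"), seed = 1L) {
  pipeline_config(out_dir = out_dir, seed = seed, overrides = list(
    simulation = list(n_genes = 600L, n_cells = 400L, n_clusters = 4L,
                      isg_panel_size = 48L, n_deg = 30L,
                      genome_n_seqs = 2L, seq_len = 30000L,
                      n_target_genes = 5L),
    composition = list(n_perm = 200L)))
}
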
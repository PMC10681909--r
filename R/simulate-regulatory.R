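#' Simulate genome, genes, peaks, PWMs and planted motif occurrences
#'
#' Generates i.i.d. background sequences, tiles genes (with strand) onto
#' them, places 1-5 non-overlapping peaks per gene inside the gene body or
#' its 2-kb strand-aware promoter, builds high-information PWMs grouped into
#' TF families, and plants motif consensus strings into peaks by
#' substitution. Peaks of designated target genes receive
#' `target_density_multiplier` times the base planting rate; families within
#' one co-occurrence block are co-planted into the same peaks with
#' probability `co_plant_prob`, producing recoverable correlation structure.
#' Per-population accessibility counts make target-gene peaks more
#' accessible in the designated population.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character), `genes` (annotation
#'   data.frame), `peaks` (peak data.frame), `motifs` (`pwm_collection`),
#'   `family_map` (named character), `access` (accessibility data.frame) and
#'   `truth` (target gene ids, planted hit-count matrix, family blocks,
#'   designated population).
#' @export
simulate_regulatory <- function(config) {
  config <- validate_config(config)
  if (config$motif_len > 50)
    abort_config("config field 'motif_len' unreasonably large (> 50)")
  with_seed(derive_seed(config$seed, "regulatory"), {
    m <- config$motif_len
    bases <- c("A", "C", "G", "T")

    genome <- vapply(seq_len(config$genome_n_seqs), function(i)
      paste(sample(bases, config$seq_len, replace = TRUE), collapse = ""),
      "")
    names(genome) <- sprintf("chr%d", seq_along(genome))

    # PWMs: sharp consensus (0.85 / 0.05) so planted strings score highly
    motif_ids <- sprintf("motif_%d", seq_len(config$n_motifs))
    consensus <- vapply(motif_ids, function(id)
      paste(sample(bases, m, replace = TRUE), collapse = ""), "")
    motifs <- lapply(seq_along(motif_ids), function(k) {
      mat <- matrix(0.05, m, 4, dimnames = list(NULL, bases))
      idx <- match(strsplit(consensus[k], "")[[1]], bases)
      mat[cbind(seq_len(m), idx)] <- 0.85
      list(motif_id = motif_ids[k], tf_name = sprintf("TF%d", k),
           matrix = mat)
    })
    names(motifs) <- motif_ids
    class(motifs) <- "pwm_collection"

    families <- sprintf("FAM%d", seq_len(config$n_families))
    family_map <- setNames(
      families[(seq_len(config$n_motifs) - 1L) %% config$n_families + 1L],
      motif_ids)
    block_of_family <- (seq_len(config$n_families) - 1L) %%
      config$n_family_blocks + 1L
    family_blocks <- split(families, block_of_family)
    names(family_blocks) <- sprintf("block%s", names(family_blocks))

    # tile genes: 2 kb clearance both sides so promoters stay on-chromosome
    glen_range <- c(500L, 1500L)
    slot_pad <- 2000L + 500L
    genes <- list()
    gi <- 0L
    for (chrom in names(genome)) {
      pos <- 2000L
      repeat {
        glen <- sample(glen_range[1]:glen_range[2], 1L)
        if (pos + glen + slot_pad > config$seq_len || gi >= config$n_genes)
          break
        gi <- gi + 1L
        genes[[gi]] <- data.frame(
          gene_id = sprintf("gene_%d", gi), chrom = chrom,
          start = pos, end = pos + glen,
          strand = sample(c("+", "-"), 1L))
        pos <- pos + glen + slot_pad
      }
    }
    genes <- do.call(rbind, genes)
    if (is.null(genes) || nrow(genes) < 2L)
      abort_config("genome too small to tile any genes; increase seq_len")
    if (config$n_target_genes >= nrow(genes))
      abort_config(sprintf(
        "config field 'n_target_genes' (%d) must be below the %d genes that fit the genome",
        config$n_target_genes, nrow(genes)))
    target_gene_ids <- sort(sample(genes$gene_id, config$n_target_genes))

    # peaks: wholly inside body + strand-aware promoter; non-overlapping
    peaks <- list(); peak_gene <- character(0); pi <- 0L
    for (g in seq_len(nrow(genes))) {
      a_lo <- if (genes$strand[g] == "+") genes$start[g] - 2000L
              else genes$start[g]
      a_hi <- if (genes$strand[g] == "+") genes$end[g]
              else genes$end[g] + 2000L
      placed <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(sample(1:5, 1L))) {
        plen <- sample(200:500, 1L)
        for (try in 1:20) {
          s <- a_lo + sample.int(a_hi - plen - a_lo + 1L, 1L) - 1L
          if (!nrow(placed) ||
              all(s + plen <= placed[, 1] | s >= placed[, 2])) {
            placed <- rbind(placed, c(s, s + plen))
            pi <- pi + 1L
            peaks[[pi]] <- data.frame(
              peak_id = sprintf("peak_%d", pi), chrom = genes$chrom[g],
              start = s, end = s + plen)
            peak_gene[pi] <- genes$gene_id[g]
            break
          }
        }
      }
    }
    peaks <- do.call(rbind, peaks)

    # Co-occurrence structure: target-gene peaks are co-planted by the
    # target family blocks; background peaks by a cross-cutting partition
    # (different regulatory grammar away from the target genes), so block
    # communities are recoverable at target peaks and dissolve elsewhere.
    background_blocks <- split(
      families, ceiling(seq_along(families) /
                          ceiling(config$n_families / config$n_family_blocks)))
    names(background_blocks) <- sprintf("bg_block%s", names(background_blocks))

    genome_chars <- lapply(genome, function(s) strsplit(s, "")[[1]])
    planted <- matrix(0L, nrow(peaks), config$n_motifs,
                      dimnames = list(peaks$peak_id, motif_ids))
    motifs_of_family <- split(motif_ids, family_map[motif_ids])
    is_target_peak <- peak_gene %in% target_gene_ids
    # plant_rate is the expected number of planted occurrences per
    # background peak; events are normalized by the expected motifs/event
    motifs_per_event <- config$co_plant_prob *
      mean(lengths(family_blocks))
    for (p in seq_len(nrow(peaks))) {
      rate <- config$plant_rate / motifs_per_event *
        if (is_target_peak[p]) config$target_density_multiplier else 1
      blocks_here <- if (is_target_peak[p]) family_blocks
                     else background_blocks
      n_events <- stats::rpois(1L, rate)
      if (n_events == 0L) next
      plen <- peaks$end[p] - peaks$start[p]
      occupied <- rep(FALSE, plen)
      for (ev in seq_len(n_events)) {
        block <- blocks_here[[sample(length(blocks_here), 1L)]]
        for (fam in block) {
          if (runif(1) > config$co_plant_prob) next
          mid <- sample(motifs_of_family[[fam]], 1L)
          free <- which(vapply(0:(plen - m), function(o)
            !any(occupied[(o + 1):(o + m)]), TRUE))
          if (!length(free)) next
          off <- free[sample(length(free), 1L)] - 1L
          word <- consensus[mid]
          if (runif(1) < 0.5) word <- revcomp(word)
          gpos <- peaks$start[p] + off  # 0-based genome offset
          genome_chars[[peaks$chrom[p]]][(gpos + 1):(gpos + m)] <-
            strsplit(word, "")[[1]]
          occupied[(off + 1):(off + m)] <- TRUE
          planted[p, mid] <- planted[p, mid] + 1L
        }
      }
    }
    genome <- vapply(genome_chars, paste, "", collapse = "")

    # accessibility: target-gene peaks more open in the designated population
    pops <- c("popA", "popB")
    access <- data.frame(row.names = peaks$peak_id)
    for (pop in pops) access[[pop]] <- rgamma(nrow(peaks), 4, scale = 0.5) + 0.1
    access[is_target_peak, "popA"] <-
      access[is_target_peak, "popA"] * config$access_multiplier

    list(genome = genome, genes = genes, peaks = peaks, motifs = motifs,
         family_map = family_map, access = access,
         truth = list(
           target_gene_ids = target_gene_ids,
           peak_gene = setNames(peak_gene, peaks$peak_id),
           planted_hit_counts = planted,
           family_blocks = family_blocks,
           background_blocks = background_blocks,
           consensus = consensus,
           designated_population = "popA",
           config = unclass(config)))
  })
}

#' Write every regulatory input to disk
#'
#' Emits `genome.fa`, `genes.tsv`, `peaks.bed`, `motifs.meme`,
#' `family_map.tsv`, `accessibility.tsv` and `ground_truth.json` under
#' `dir`.
#'
#' @param sim Output of [simulate_regulatory()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_regulatory_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gene_annotation(sim$genes, file.path(dir, "genes.tsv"))
  write_bed_peaks(sim$peaks, file.path(dir, "peaks.bed"))
  write_meme_motifs(sim$motifs, file.path(dir, "motifs.meme"))
  write_family_map(sim$family_map, file.path(dir, "family_map.tsv"),
                   vapply(sim$motifs, `[[`, "", "tf_name"))
  write_accessibility(sim$access, file.path(dir, "accessibility.tsv"))
  truth <- sim$truth
  truth$planted_hit_counts <- NULL  # matrix serialized separately
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(cbind(peak_id = rownames(sim$truth$planted_hit_counts),
                    as.data.frame(sim$truth$planted_hit_counts)),
              file.path(dir, "planted_hit_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
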
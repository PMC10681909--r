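#' Assign peaks to genes (gene body + 2-kb promoter)
#'
#' A peak is assigned to a gene iff the half-open peak interval intersects
#' the union of the gene body and its strand-aware promoter: `promoter_bp`
#' upstream of the TSS (TSS = `start` for `+` genes, `end` for `-` genes),
#' clipped at 0. A peak may be assigned to several genes.
#'
#' @param peaks Peak data.frame (`peak_id`, `chrom`, `start`, `end`).
#' @param genes Gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`), 0-based half-open.
#' @param promoter_bp Promoter extent upstream of the TSS.
#' @return Named list: `gene_id -> character vector of peak_ids`, with
#'   attribute `promoter_bp`.
#' @export
assign_peaks <- function(peaks, genes, promoter_bp = 2000L) {
  ext_start <- ifelse(genes$strand == "+",
                      pmax(0L, genes$start - promoter_bp), genes$start)
  ext_end <- ifelse(genes$strand == "+",
                    genes$end, genes$end + promoter_bp)
  out <- setNames(vector("list", nrow(genes)), genes$gene_id)
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    pi <- which(peaks$chrom == chrom)
    if (!length(pi)) next
    # half-open [a,b) vs [c,d) intersect iff a < d and c < b;
    # IRanges is 1-based closed, so [a,b) maps to [a+1, b]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(ext_start[gi] + 1L, ext_end[gi]),
      IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]))
    sp <- split(peaks$peak_id[pi[S4Vectors::subjectHits(ov)]],
                genes$gene_id[gi[S4Vectors::queryHits(ov)]])
    for (g in names(sp)) out[[g]] <- c(out[[g]], sp[[g]])
  }
  out <- lapply(out, function(v) if (is.null(v)) character(0) else v)
  attr(out, "promoter_bp") <- promoter_bp
  out
}

#' Normalized Motif Score (NMS)
#'
#' For gene `g` and TF (or family) `T`:
#' `NMS(g, T) = sum over assigned peaks i of a_i * m_i(T) / L_i`, where
#' `a_i` is the peak's mean accessibility count in the chosen population,
#' `m_i(T)` its motif hit count (summed over member motifs at family level)
#' and `L_i` its length in kilobases.
#'
#' @param hits A `motif_hit_matrix` (or a bare peaks x motifs count matrix).
#' @param peaks Peak data.frame.
#' @param assignment Output of [assign_peaks()].
#' @param access Accessibility data.frame (rownames = peak ids, one column
#'   per population).
#' @param population Which accessibility column supplies `a_i`.
#' @param level `"tf"` (per motif) or `"family"` (summed over members).
#' @param family_map Named `motif_id -> family` vector (family level only).
#' @return Numeric genes x TFs (or genes x families) matrix.
#' @export
compute_nms <- function(hits, peaks, assignment, access, population,
                        level = c("tf", "family"), family_map = NULL) {
  level <- match.arg(level)
  counts <- if (inherits(hits, "motif_hit_matrix")) hits$counts else hits
  if (!population %in% colnames(access))
    abort_input(sprintf("population '%s' not in accessibility table",
                        population))
  if (level == "family" && is.null(family_map))
    abort_input("family level needs a family_map")
  a <- access[rownames(counts), population]
  len_kb <- (peaks$end - peaks$start)[match(rownames(counts),
                                            peaks$peak_id)] / 1000
  weight <- a / len_kb
  nms <- matrix(0, length(assignment), ncol(counts),
                dimnames = list(names(assignment), colnames(counts)))
  for (g in seq_along(assignment)) {
    pk <- match(assignment[[g]], rownames(counts))
    if (length(pk))
      nms[g, ] <- colSums(counts[pk, , drop = FALSE] * weight[pk])
  }
  if (level == "family") {
    unmapped <- setdiff(colnames(nms), names(family_map))
    if (length(unmapped))
      abort_input(sprintf("motif(s) without a family: %s",
                          paste(unmapped, collapse = ", ")))
    # aggregate per-motif NMS columns so family NMS is the exact (same
    # floating-point op) sum of its members' NMS values
    fams <- sort(unique(unname(family_map[colnames(nms)])))
    out <- matrix(0, nrow(nms), length(fams),
                  dimnames = list(rownames(nms), fams))
    for (f in fams) {
      members <- colnames(nms)[family_map[colnames(nms)] == f]
      out[, f] <- rowSums(nms[, members, drop = FALSE])
    }
    nms <- out
  }
  nms
}

#' Compare NMS between a gene set and background genes
#'
#' Two-sided Mann-Whitney U test on the NMS values of the two gene sets for
#' one TF or family, reporting the U statistic, p-value and the difference
#' of medians.
#'
#' @param nms NMS matrix from [compute_nms()].
#' @param deg_genes,background_genes Gene-id vectors (disjoint after
#'   intersection with the table; each needs at least 5 genes).
#' @param tf_or_family Column of `nms` to compare.
#' @return List: `statistic`, `p_value`,
#'   `effect` (median(deg) - median(background)).
#' @export
compare_nms <- function(nms, deg_genes, background_genes, tf_or_family) {
  if (!tf_or_family %in% colnames(nms))
    abort_input(sprintf("'%s' not a column of the NMS table", tf_or_family))
  g1 <- intersect(deg_genes, rownames(nms))
  g2 <- intersect(background_genes, rownames(nms))
  if (!length(g1) || !length(g2))
    abort_input("gene set has empty intersection with the NMS table")
  if (length(intersect(g1, g2)))
    abort_input("gene sets must be disjoint")
  if (length(g1) < 5 || length(g2) < 5)
    abort_input("each gene set needs at least 5 genes in the table")
  v1 <- nms[g1, tf_or_family]
  v2 <- nms[g2, tf_or_family]
  if (var(c(v1, v2)) == 0) {  # fully tied: no evidence either way
    return(list(statistic = length(v1) * length(v2) / 2, p_value = 1,
                effect = 0))
  }
  ht <- suppressWarnings(wilcox.test(v1, v2))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       effect = median(v1) - median(v2))
}
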
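#' QC thresholds
#'
#' Defaults follow the cutoffs used throughout: UMI in \[500, 25000\],
#' mitochondrial fraction below 0.5% (0.005), doublet score below 0.25%
#' (0.0025); for snATAC nuclei, fraction of reads in peaks (FRiP) at least
#' 15% and peak-region fragments in \[30000, 1500000\].
#'
#' @param min_umi,max_umi UMI bounds per cell.
#' @param max_mito_fraction Maximum mitochondrial read fraction.
#' @param max_doublet_score Maximum doublet score.
#' @param atac_min_frip Minimum fraction of fragments in peaks per nucleus.
#' @param atac_min_fragments,atac_max_fragments Peak-region fragment bounds.
#' @return A validated `qc_params` list.
#' @export
qc_params <- function(min_umi = 500, max_umi = 25000,
                      max_mito_fraction = 0.005,
                      max_doublet_score = 0.0025,
                      atac_min_frip = 0.15,
                      atac_min_fragments = 30000,
                      atac_max_fragments = 1500000) {
  p <- list(min_umi = min_umi, max_umi = max_umi,
            max_mito_fraction = max_mito_fraction,
            max_doublet_score = max_doublet_score,
            atac_min_frip = atac_min_frip,
            atac_min_fragments = atac_min_fragments,
            atac_max_fragments = atac_max_fragments)
  if (p$min_umi >= p$max_umi)
    abort_config("qc: min_umi must be below max_umi")
  if (p$atac_min_fragments >= p$atac_max_fragments)
    abort_config("qc: atac_min_fragments must be below atac_max_fragments")
  for (f in c("max_mito_fraction", "max_doublet_score", "atac_min_frip"))
    if (p[[f]] < 0 || p[[f]] > 1)
      abort_config(sprintf("qc: %s must lie in [0,1]", f))
  structure(p, class = "qc_params")
}

#' Filter cells on QC covariates
#'
#' Retains cells passing every rule. Removal counts are attributed to the
#' first failing rule, evaluated in fixed order: `min_umi`, `max_umi`,
#' `mito`, `doublet`.
#'
#' @param x An `expression_matrix` with `mito_fraction` and `doublet_score`
#'   metadata columns.
#' @param params A [qc_params()].
#' @return List with `matrix` (filtered `expression_matrix`) and `report`
#'   (named removal counts plus `retained`).
#' @export
qc_filter_cells <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "expression_matrix"))
  md <- x$metadata
  for (col in c("mito_fraction", "doublet_score", "umi_total"))
    if (is.null(md[[col]]))
      abort_input(sprintf("metadata column '%s' missing", col))
  fail <- cbind(
    min_umi = md$umi_total < params$min_umi,
    max_umi = md$umi_total > params$max_umi,
    mito    = md$mito_fraction > params$max_mito_fraction,
    doublet = md$doublet_score > params$max_doublet_score)
  first <- apply(fail, 1L, function(r) if (any(r)) which(r)[1] else 0L)
  report <- c(min_umi = sum(first == 1), max_umi = sum(first == 2),
              mito = sum(first == 3), doublet = sum(first == 4))
  keep <- first == 0L
  report <- c(as.list(report), retained = sum(keep))
  out <- expression_matrix(x$counts[, keep, drop = FALSE],
                           md[keep, , drop = FALSE])
  list(matrix = out, report = report)
}

#' Filter snATAC nuclei on FRiP and fragment counts
#'
#' Same mechanism as [qc_filter_cells()], applied to a per-nucleus table.
#' Rule order for the report: `frip`, `min_fragments`, `max_fragments`.
#'
#' @param nuclei data.frame with columns `frip` and `fragments`.
#' @param params A [qc_params()].
#' @return List with `nuclei` (filtered table) and `report`.
#' @export
qc_filter_nuclei <- function(nuclei, params = qc_params()) {
  for (col in c("frip", "fragments"))
    if (is.null(nuclei[[col]]))
      abort_input(sprintf("nuclei column '%s' missing", col))
  fail <- cbind(
    frip = nuclei$frip < params$atac_min_frip,
    min_fragments = nuclei$fragments < params$atac_min_fragments,
    max_fragments = nuclei$fragments > params$atac_max_fragments)
  first <- apply(fail, 1L, function(r) if (any(r)) which(r)[1] else 0L)
  keep <- first == 0L
  report <- list(frip = sum(first == 1), min_fragments = sum(first == 2),
                 max_fragments = sum(first == 3), retained = sum(keep))
  list(nuclei = nuclei[keep, , drop = FALSE], report = report)
}

#' Library-size log normalization
#'
#' `value = ln(1 + count * scale / umi_total)`, preserving sparsity (zero
#' counts stay exactly zero).
#'
#' @param x An `expression_matrix` with no zero-total cells.
#' @param scale Target library size (default 1e4).
#' @return A sparse genes x cells matrix of normalized values, with the cell
#'   metadata attached as attribute `metadata`.
#' @export
normalize_log <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "expression_matrix"))
  tot <- x$metadata$umi_total
  if (any(tot == 0))
    abort_input("zero-total cell(s) present; run qc_filter_cells first")
  norm <- x$counts
  norm@x <- log1p(norm@x * scale / rep.int(tot, diff(norm@p)))
  attr(norm, "metadata") <- x$metadata
  norm
}
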
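#' Construct an expression matrix container
#'
#' Genes x cells sparse integer counts plus aligned per-cell metadata
#' (condition, cluster, QC covariates). `umi_total` is recomputed from the
#' column sums if absent and validated if present.
#'
#' @param counts A sparse (or dense) genes x cells matrix with dimnames.
#' @param metadata A data.frame with one row per cell, rownames = cell ids.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(counts, metadata) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_input("counts must carry gene ids (rownames) and cell ids (colnames)")
  if (!setequal(rownames(metadata), colnames(counts)))
    abort_input("metadata rownames must match count matrix cell ids")
  metadata <- metadata[colnames(counts), , drop = FALSE]
  csum <- Matrix::colSums(counts)
  if (is.null(metadata$umi_total)) {
    metadata$umi_total <- csum
  } else if (any(abs(metadata$umi_total - csum) > 1e-8)) {
    abort_input("umi_total metadata disagrees with count column sums")
  }
  structure(list(counts = counts, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%d metadata columns)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$metadata)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Read a gene x cell count matrix (MTX + sidecars)
#'
#' @param mtx_path Matrix Market file (genes x cells).
#' @param features_path One gene id per line (first tab field).
#' @param barcodes_path One cell id per line.
#' @param metadata_path Optional TSV with a `cell_id` column plus per-cell
#'   metadata; every barcode must be present.
#' @return An `expression_matrix`.
#' @export
read_counts <- function(mtx_path, features_path, barcodes_path,
                        metadata_path = NULL) {
  # a numerically symmetric matrix round-trips through MTX "symmetric"
  # storage; force the general class before attaching asymmetric dimnames
  m <- methods::as(methods::as(Matrix::readMM(mtx_path), "CsparseMatrix"),
                   "generalMatrix")
  genes <- read.table(features_path, sep = "\t",
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.table(barcodes_path, sep = "\t",
                      stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    abort_format(sprintf(
      "MTX dimensions %d x %d do not match %d features / %d barcodes",
      nrow(m), ncol(m), length(genes), length(cells)))
  dimnames(m) <- list(genes, cells)
  if (!is.null(metadata_path)) {
    md <- read.table(metadata_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    if (is.null(md$cell_id)) abort_format("metadata must have a cell_id column")
    missing <- setdiff(cells, md$cell_id)
    if (length(missing))
      abort_format(sprintf("metadata missing barcode(s): %s",
                           paste(utils::head(missing, 5), collapse = ", ")))
    rownames(md) <- md$cell_id
    md <- md[cells, setdiff(names(md), "cell_id"), drop = FALSE]
  } else {
    md <- data.frame(row.names = cells)
  }
  expression_matrix(m, md)
}

#' Write an expression matrix as MTX + sidecar TSVs
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `cell_metadata.tsv`
#' under `dir`.
#'
#' @param x An `expression_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  md <- cbind(cell_id = rownames(x$metadata), x$metadata)
  write.table(md, file.path(dir, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---- interval tables (0-based half-open throughout) -------------------------

check_intervals <- function(df, what) {
  if (any(df$start >= df$end))
    abort_format(sprintf("%s: start must be < end (0-based half-open)", what))
  if (any(df$start < 0)) abort_format(sprintf("%s: negative start", what))
  invisible(df)
}

#' Read peaks from BED
#'
#' BED intervals are 0-based half-open. Columns beyond the first four are
#' ignored; a missing name column yields `peak_1..n`.
#'
#' @param path BED file.
#' @return data.frame with `peak_id`, `chrom`, `start`, `end`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("BED file not found: %s", path))
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$peak_id <- if (ncol(df) >= 4) as.character(df[[4]])
                else sprintf("peak_%d", seq_len(nrow(df)))
  if (anyDuplicated(df$peak_id)) abort_format("duplicate peak ids in BED")
  check_intervals(df, "BED")
  df[, c("peak_id", "chrom", "start", "end")]
}

#' Write peaks as BED6
#' @param peaks data.frame with `peak_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    0L, ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation (TSV)
#'
#' Header columns: `gene_id`, `chrom`, `start`, `end`, `strand`; coordinates
#' 0-based half-open, strand `+` or `-`.
#'
#' @param path TSV path.
#' @return data.frame of gene records.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path))
    abort_input(sprintf("gene annotation not found: %s", path))
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    abort_format(sprintf("gene annotation needs columns: %s",
                         paste(need, collapse = ", ")))
  if (anyDuplicated(df$gene_id)) abort_format("duplicate gene ids")
  if (!all(df$strand %in% c("+", "-")))
    abort_format("strand must be '+' or '-'")
  check_intervals(df, "gene annotation")
  df[, need]
}

#' Write gene annotation (TSV)
#' @param genes data.frame as from [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-population peak accessibility (TSV)
#'
#' One row per peak (`peak_id` column) and one numeric column per population
#' holding the population's mean fragment count in that peak.
#'
#' @param path TSV path.
#' @return data.frame, rownames = peak ids, one column per population.
#' @export
read_accessibility <- function(path) {
  if (!file.exists(path))
    abort_input(sprintf("accessibility table not found: %s", path))
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (is.null(df$peak_id)) abort_format("accessibility table needs peak_id")
  rownames(df) <- df$peak_id
  df$peak_id <- NULL
  if (any(as.matrix(df) < 0)) abort_format("negative accessibility count")
  df
}

#' Write per-population peak accessibility (TSV)
#' @param access data.frame, rownames = peak ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(access, path) {
  write.table(cbind(peak_id = rownames(access), access), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
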
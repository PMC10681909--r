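#' Read position probability matrices in MEME minimal format
#'
#' Parses the MEME "minimal" text dialect (the common interchange format for
#' CisBP-style PWMs). The file must declare the ACGT alphabet. Probability
#' rows whose sum is within `1e-3` of 1 are renormalized; larger departures
#' are rejected.
#'
#' @param path Path to a MEME minimal file.
#' @return A `pwm_collection`: a list of motif records, each with
#'   `motif_id`, `tf_name` and `matrix` (positions x `A,C,G,T` probabilities).
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("MEME file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  alpha <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (!length(alpha) || !grepl("ACGT", gsub("\\s", "", alpha[1])))
    abort_format("MEME file must declare 'ALPHABET= ACGT'")
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) abort_format("no MOTIF header found in MEME file")
  motifs <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    hdr <- strsplit(trimws(block[1]), "\\s+")[[1]]
    motif_id <- hdr[2]
    tf_name <- if (length(hdr) >= 3) hdr[3] else motif_id
    if (is.na(motif_id) || !nzchar(motif_id))
      abort_format("MOTIF header without an identifier")
    lp <- grep("^letter-probability matrix", block)
    if (!length(lp))
      abort_format(sprintf("motif '%s': missing letter-probability matrix",
                           motif_id))
    w <- suppressWarnings(as.integer(
      sub(".*\\bw=\\s*(\\d+).*", "\\1", block[lp[1]])))
    rows <- block[-seq_len(lp[1])]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    if (!is.na(w)) rows <- utils::head(rows, w)
    if (!length(rows))
      abort_format(sprintf("motif '%s': empty probability matrix", motif_id))
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (ncol(mat) != 4L || anyNA(mat))
      abort_format(sprintf("motif '%s': malformed probability row", motif_id))
    if (any(mat < 0))
      abort_format(sprintf("motif '%s': negative probability", motif_id))
    rs <- rowSums(mat)
    off <- which(abs(rs - 1) > 1e-3)
    if (length(off))
      abort_format(sprintf(
        "motif '%s': probability row %d sums to %.6g (tolerance 1e-3)",
        motif_id, off[1], rs[off[1]]))
    mat <- mat / rs
    colnames(mat) <- c("A", "C", "G", "T")
    motifs[[k]] <- list(motif_id = motif_id, tf_name = tf_name, matrix = mat)
  }
  ids <- vapply(motifs, `[[`, "", "motif_id")
  if (anyDuplicated(ids))
    abort_format(sprintf("duplicate motif id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(motifs) <- ids
  structure(motifs, class = "pwm_collection")
}

#' Write a PWM collection in MEME minimal format
#'
#' @param motifs A `pwm_collection` (see [read_meme_motifs()]).
#' @param path Output path.
#' @param background Background base frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f",
            background[1], background[2], background[3], background[4]),
    ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id, m$tf_name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$matrix)), con)
    writeLines(apply(m$matrix, 1L, function(r)
      paste(sprintf("%.9f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif-to-family map
#'
#' Tab-delimited file with header `motif_id`, `tf_name`, `family`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: `motif_id -> family`.
#' @export
read_family_map <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("family map not found: %s", path))
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("motif_id", "family")
  if (!all(need %in% names(df)))
    abort_format(sprintf("family map must have columns %s",
                         paste(need, collapse = ", ")))
  if (anyDuplicated(df$motif_id))
    abort_format("family map assigns a motif more than one family")
  setNames(as.character(df$family), df$motif_id)
}

#' Write a motif-to-family map
#' @param fam Named character vector `motif_id -> family`.
#' @param tf_names Optional named vector `motif_id -> tf_name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_map <- function(fam, path, tf_names = NULL) {
  tf <- if (is.null(tf_names)) names(fam) else unname(tf_names[names(fam)])
  write.table(
    data.frame(motif_id = names(fam), tf_name = tf, family = unname(fam)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
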
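#' Read genome sequences from FASTA
#'
#' Reads a (possibly line-wrapped, possibly gzipped) FASTA file into a named
#' character vector of uppercase DNA sequences. Only `A`, `C`, `G`, `T`, `N`
#' are accepted; lowercase input is uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort_format(sprintf("duplicate FASTA header(s): %s",
                         paste(dup, collapse = ", ")))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]]))
      abort_format(sprintf("empty sequence for '%s'", ids[[i]]))
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0)
      abort_format(sprintf(
        "non-IUPAC character '%s' in sequence '%s' at position %d",
        substr(seqs[[i]], bad, bad), ids[[i]], as.integer(bad)))
  }
  seqs
}

#' Write genome sequences to FASTA
#'
#' @param seqs Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param seqs Character vector over `{A,C,G,T,N}`.
#' @return Reverse complement of each element.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}
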
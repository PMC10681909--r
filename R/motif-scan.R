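BASES <- c("A", "C", "G", "T")

#' Build a log2-odds scoring matrix from a PWM
#'
#' `entry(pos, b) = log2((p(pos, b) + pseudocount * bg(b)) /
#' ((1 + pseudocount) * bg(b)))`, the standard FIMO-style scoring model.
#'
#' @param pwm A motif record (`motif_id`, `tf_name`, `matrix`) or a bare
#'   positions x 4 probability matrix.
#' @param background Background base frequencies (positive, sum 1).
#' @param pseudocount Pseudocount fraction added as `pseudocount * bg(b)`.
#' @return A `logodds_matrix`: list with `motif_id`, `lo` (positions x 4
#'   log2-odds), `background`, `pseudocount`.
#' @export
build_logodds <- function(pwm, background = rep(0.25, 4),
                          pseudocount = 0.001) {
  mat <- if (is.list(pwm)) pwm$matrix else pwm
  motif_id <- if (is.list(pwm)) pwm$motif_id else "motif"
  if (length(background) != 4 || any(background <= 0))
    abort_input("background must be 4 positive frequencies")
  background <- background / sum(background)
  lo <- log2(sweep(mat, 2, background * pseudocount, "+") /
               rep((1 + pseudocount) * background, each = nrow(mat)))
  colnames(lo) <- BASES
  structure(list(motif_id = motif_id, lo = lo, background = background,
                 pseudocount = pseudocount), class = "logodds_matrix")
}

#' Exact score threshold for a p-value cutoff
#'
#' Computes the exact distribution of the total window score under the
#' i.i.d. background model by position-wise convolution of
#' integer-discretized per-position scores (`granularity` units per log2
#' unit), then returns the smallest score whose tail probability is at most
#' `p_cutoff`. The tail mass at the returned threshold is guaranteed to be
#' `<= p_cutoff`; if even the maximal score is too probable the threshold is
#' `Inf` and scanning yields no hits.
#'
#' @param lo A `logodds_matrix`.
#' @param p_cutoff Tail probability cutoff (default 1e-4, the standard
#'   FIMO motif-match cutoff).
#' @param granularity Integer score units per log2 unit.
#' @return List: `threshold` (real score), `threshold_int` (discretized),
#'   `granularity`, `attained` (tail probability at the threshold),
#'   `dist` (data.frame `score_int`, `prob` over the full support).
#' @export
exact_threshold <- function(lo, p_cutoff = 1e-4, granularity = 1000L) {
  if (p_cutoff <= 0 || p_cutoff >= 1)
    abort_input("p_cutoff must lie in (0,1)")
  smat <- round(lo$lo * granularity)
  w <- nrow(smat)
  support <- sum(apply(smat, 1, max) - apply(smat, 1, min)) + 1
  if (support > 5e6)
    abort_input(sprintf(
      "score support too large (%g values) for motif of length %d; lower the granularity",
      support, w))
  bg <- lo$background
  lo_min <- cumsum(apply(smat, 1, min))
  lo_max <- cumsum(apply(smat, 1, max))
  # pmf over integer scores, position by position
  pmf <- numeric(lo_max[1] - lo_min[1] + 1)
  for (b in 1:4) {
    i <- smat[1, b] - lo_min[1] + 1
    pmf[i] <- pmf[i] + bg[b]
  }
  if (w > 1) for (pos in 2:w) {
    new <- numeric(lo_max[pos] - lo_min[pos] + 1)
    off_old <- lo_min[pos - 1]
    for (b in 1:4) {
      sh <- smat[pos, b]
      idx <- seq_along(pmf) + (off_old + sh - lo_min[pos])
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new
  }
  scores <- seq(lo_min[w], lo_max[w])
  keep <- pmf > 0
  tail_p <- rev(cumsum(rev(pmf)))
  ok <- which(tail_p <= p_cutoff)
  if (!length(ok)) {
    thr_int <- Inf; attained <- 0
  } else {
    thr_int <- scores[ok[1]]
    attained <- tail_p[ok[1]]
  }
  list(threshold = thr_int / granularity, threshold_int = thr_int,
       granularity = granularity, attained = attained,
       dist = data.frame(score_int = scores[keep], prob = pmf[keep]))
}

# integer-encode a DNA string: A,C,G,T -> 1..4, anything else NA
encode_dna <- function(s) {
  match(strsplit(s, "")[[1]], BASES)
}

# score every window of an encoded sequence with an integer score matrix;
# windows touching NA (i.e. N) come back NA
score_windows <- function(code, smat_int) {
  m <- nrow(smat_int)
  L <- length(code)
  if (L < m) return(numeric(0))
  n_win <- L - m + 1L
  s <- numeric(n_win)
  for (pos in seq_len(m))
    s <- s + smat_int[pos, code[pos:(pos + n_win - 1L)]]
  s
}

#' Estimate a 0-order background from peak sequences
#' @param genome Named character vector of sequences.
#' @param peaks Peak data.frame (`chrom`, `start`, `end`; 0-based half-open).
#' @return Frequencies of A, C, G, T over the peak bases (N ignored).
#' @export
estimate_background <- function(genome, peaks) {
  seqs <- peak_sequences(genome, peaks)
  tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                      levels = BASES))
  as.numeric(tab / sum(tab))
}

#' Extract peak sequences from a genome
#' @inheritParams estimate_background
#' @return Character vector of peak sequences, named by peak id.
#' @export
peak_sequences <- function(genome, peaks) {
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing))
    abort_input(sprintf("chromosome(s) missing from genome: %s",
                        paste(missing, collapse = ", ")))
  setNames(substr(genome[peaks$chrom], peaks$start + 1L, peaks$end),
           peaks$peak_id)
}

#' Scan peaks for motif matches at an exact p-value threshold
#'
#' Scores every window of every peak on the forward and (optionally)
#' reverse-complement strand with each motif's log2-odds matrix and counts
#' windows at or above the motif's [exact_threshold()]. Windows containing
#' `N` never match; overlapping qualifying windows are each counted.
#'
#' @param genome Named character vector of sequences.
#' @param peaks Peak data.frame (`peak_id`, `chrom`, `start`, `end`).
#' @param motifs A `pwm_collection`.
#' @param p_cutoff Exact p-value cutoff per window.
#' @param both_strands Scan the reverse-complement strand too.
#' @param background Background base frequencies (default uniform).
#' @param pseudocount,granularity Passed to [build_logodds()] /
#'   [exact_threshold()].
#' @param keep_hits Also return per-hit records.
#' @return A `motif_hit_matrix`: list with `counts` (peaks x motifs integer
#'   matrix), `thresholds` (per-motif threshold info) and, if requested,
#'   `hits` (data.frame `peak_id`, `motif_id`, `offset` (0-based within the
#'   peak), `strand`, `score`).
#' @export
scan_peaks <- function(genome, peaks, motifs, p_cutoff = 1e-4,
                       both_strands = TRUE, background = rep(0.25, 4),
                       pseudocount = 0.001, granularity = 1000L,
                       keep_hits = FALSE) {
  seqs <- peak_sequences(genome, peaks)
  counts <- matrix(0L, nrow(peaks), length(motifs),
                   dimnames = list(peaks$peak_id,
                                   unname(vapply(motifs, `[[`, "",
                                                 "motif_id"))))
  thresholds <- list()
  hits <- list()
  max_w <- max(vapply(motifs, function(m) nrow(m$matrix), 0L))
  # concatenate peaks with N spacers: windows can never span two peaks
  spacer <- strrep("N", max_w)
  concat <- paste(seqs, collapse = spacer)
  code <- encode_dna(concat)
  peak_off <- cumsum(c(0L, utils::head(nchar(seqs) + max_w, -1L)))

  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    lo <- build_logodds(m, background, pseudocount)
    thr <- exact_threshold(lo, p_cutoff, granularity)
    thresholds[[m$motif_id]] <- thr
    if (!is.finite(thr$threshold_int)) next
    smat_int <- round(lo$lo * granularity)
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      sm <- if (st == "+") smat_int
            else smat_int[rev(seq_len(nrow(smat_int))), c(4:1), drop = FALSE]
      sc <- score_windows(code, sm)
      hit_at <- which(!is.na(sc) & sc >= thr$threshold_int)
      if (!length(hit_at)) next
      pk <- findInterval(hit_at - 1L, peak_off)
      counts[, mi] <- counts[, mi] + tabulate(pk, nrow(peaks))
      if (keep_hits)
        hits[[length(hits) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[pk], motif_id = m$motif_id,
          offset = hit_at - 1L - peak_off[pk], strand = st,
          score = sc[hit_at] / granularity)
    }
  }
  out <- list(counts = counts, thresholds = thresholds)
  if (keep_hits)
    out$hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(peak_id = character(0), motif_id = character(0),
                 offset = integer(0), strand = character(0),
                 score = numeric(0))
  structure(out, class = "motif_hit_matrix")
}
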
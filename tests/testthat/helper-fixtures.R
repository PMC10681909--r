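# Fixtures built in code; nothing binary ships with the package.

# tiny expression matrix with fully controlled entries
tiny_expression <- function(counts, condition = NULL, cluster = NULL,
                            mito = 0, doublet = 0) {
  ng <- nrow(counts); nc <- ncol(counts)
  dimnames(counts) <- list(sprintf("g%d", seq_len(ng)),
                           sprintf("c%d", seq_len(nc)))
  md <- data.frame(
    condition = if (is.null(condition)) rep("a", nc) else condition,
    cluster = if (is.null(cluster)) rep("k1", nc) else cluster,
    mito_fraction = rep_len(mito, nc),
    doublet_score = rep_len(doublet, nc),
    row.names = colnames(counts))
  expression_matrix(Matrix::Matrix(counts, sparse = TRUE), md)
}

# deterministic PWM whose consensus is `word` (probability p on consensus)
consensus_pwm <- function(word, p = 0.97, motif_id = "m1", tf = "TF1") {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(word, "")[[1]]
  mat <- matrix((1 - p) / 3, length(chars), 4, dimnames = list(NULL, bases))
  mat[cbind(seq_along(chars), match(chars, bases))] <- p
  structure(list(list(motif_id = motif_id, tf_name = tf, matrix = mat)),
            names = motif_id, class = "pwm_collection")
}

random_pwm_collection <- function(n, len, seed) {
  set.seed(seed)
  motifs <- lapply(seq_len(n), function(k) {
    mat <- matrix(rgamma(len * 4, 1), len, 4)
    mat <- mat / rowSums(mat)
    colnames(mat) <- c("A", "C", "G", "T")
    list(motif_id = sprintf("m%d", k), tf_name = sprintf("TF%d", k),
         matrix = mat)
  })
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")
  structure(motifs, class = "pwm_collection")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force tail probability of a discretized log-odds matrix by
# enumerating all 4^L windows (independent oracle for exact_threshold)
enumerate_tail <- function(lo, threshold_int, granularity = 1000L) {
  smat <- round(lo$lo * granularity)
  w <- nrow(smat)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(sapply(seq_len(w), function(pos) smat[pos, grid[, pos]]))
  probs <- apply(matrix(lo$background[grid], nrow(grid)), 1, prod)
  sum(probs[scores >= threshold_int])
}

# small regulatory config used across tests
small_reg_config <- function(seed = 1L, ...) {
  simulation_config(genome_n_seqs = 3L, seq_len = 40000L,
                    n_target_genes = 8L, seed = seed, ...)
}
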
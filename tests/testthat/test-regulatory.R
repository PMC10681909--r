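test_that("assign_peaks boundary arithmetic (promoter = 2 kb upstream)", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(5000L, 5000L), end = c(8000L, 8000L),
                      strand = c("+", "-"))
  peak <- function(s, e) data.frame(peak_id = "p", chrom = "chr1",
                                    start = s, end = e)
  # + strand: promoter [3000, 5000)
  expect_equal(assign_peaks(peak(3000L, 3100L), genes[1, ])$gp, "p")
  expect_length(assign_peaks(peak(2900L, 3000L), genes[1, ])$gp, 0)
  # - strand: promoter [8000, 10000)
  expect_equal(assign_peaks(peak(8000L, 8100L), genes[2, ])$gm, "p")
  expect_length(assign_peaks(peak(10000L, 10100L), genes[2, ])$gm, 0)
  # promoter clipped at 0
  g0 <- data.frame(gene_id = "g0", chrom = "chr1", start = 500L,
                   end = 1000L, strand = "+")
  expect_equal(assign_peaks(peak(0L, 10L), g0)$g0, "p")
})

test_that("assign_peaks equals the quadratic brute-force overlap oracle", {
  set.seed(13)
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:40),
    chrom = sample(c("c1", "c2"), 40, replace = TRUE),
    start = sample(0:50000, 40), strand = sample(c("+", "-"), 40, TRUE))
  genes$end <- genes$start + sample(500:3000, 40)
  peaks <- data.frame(
    peak_id = sprintf("p%d", 1:120),
    chrom = sample(c("c1", "c2"), 120, replace = TRUE),
    start = sample(0:52000, 120))
  peaks$end <- peaks$start + sample(100:600, 120)
  got <- assign_peaks(peaks, genes)
  for (g in seq_len(nrow(genes))) {
    lo <- if (genes$strand[g] == "+") max(0, genes$start[g] - 2000)
          else genes$start[g]
    hi <- if (genes$strand[g] == "+") genes$end[g]
          else genes$end[g] + 2000
    ref <- peaks$peak_id[peaks$chrom == genes$chrom[g] &
                           peaks$start < hi & peaks$end > lo]
    expect_setequal(got[[genes$gene_id[g]]], ref)
  }
})

test_that("compute_nms matches the stated formula", {
  # single peak: length 1000 bp, accessibility 2, hits 3 -> NMS 6
  peaks <- data.frame(peak_id = "p1", chrom = "c", start = 0L, end = 1000L)
  counts <- matrix(3L, 1, 1, dimnames = list("p1", "m1"))
  access <- data.frame(pop = 2, row.names = "p1")
  nms <- compute_nms(counts, peaks, list(g1 = "p1", g2 = character(0)),
                     access, "pop")
  expect_equal(unname(nms["g1", "m1"]), 6)
  expect_equal(unname(nms["g2", "m1"]), 0)
  expect_error(compute_nms(counts, peaks, list(g1 = "p1"), access, "nope"),
               class = "ifnregnet_input_error")
})

test_that("NMS table equals a loop-based recomputation; family NMS is the
           sum of member NMS; linear in accessibility and counts", {
  sim <- simulate_regulatory(small_reg_config(seed = 19))
  hits <- scan_peaks(sim$genome, sim$peaks, sim$motifs)
  assignment <- assign_peaks(sim$peaks, sim$genes)
  nms <- compute_nms(hits, sim$peaks, assignment, sim$access, "popA")

  # independent loop-based oracle
  for (g in names(assignment)) {
    for (m in colnames(hits$counts)) {
      tot <- 0
      for (pk in assignment[[g]]) {
        i <- match(pk, sim$peaks$peak_id)
        a <- sim$access[pk, "popA"]
        L <- (sim$peaks$end[i] - sim$peaks$start[i]) / 1000
        tot <- tot + a * hits$counts[pk, m] / L
      }
      expect_equal(unname(nms[g, m]), tot, tolerance = 1e-12)
    }
  }

  fam <- compute_nms(hits, sim$peaks, assignment, sim$access, "popA",
                     level = "family", family_map = sim$family_map)
  for (f in colnames(fam)) {
    members <- names(sim$family_map)[sim$family_map == f]
    expect_equal(fam[, f], rowSums(nms[, members, drop = FALSE]),
                 tolerance = 1e-12)
  }

  # linearity in accessibility
  acc2 <- sim$access
  acc2$popA <- acc2$popA * 3
  expect_equal(compute_nms(hits, sim$peaks, assignment, acc2, "popA"),
               nms * 3, tolerance = 1e-12)
  # linearity in hit counts
  expect_equal(compute_nms(hits$counts * 2L, sim$peaks, assignment,
                           sim$access, "popA"),
               nms * 2, tolerance = 1e-12)
})

test_that("per-peak length normalization is not split-invariant", {
  # halving a peak keeps a_i and m_i but halves L_i: NMS doubles, by design
  peaks1 <- data.frame(peak_id = "p1", chrom = "c", start = 0L, end = 1000L)
  peaks2 <- data.frame(peak_id = c("a", "b"), chrom = "c",
                       start = c(0L, 500L), end = c(500L, 1000L))
  counts1 <- matrix(2L, 1, 1, dimnames = list("p1", "m"))
  counts2 <- matrix(1L, 2, 1, dimnames = list(c("a", "b"), "m"))
  acc1 <- data.frame(pop = 1, row.names = "p1")
  acc2 <- data.frame(pop = c(1, 1), row.names = c("a", "b"))
  n1 <- compute_nms(counts1, peaks1, list(g = "p1"), acc1, "pop")
  n2 <- compute_nms(counts2, peaks2, list(g = c("a", "b")), acc2, "pop")
  expect_equal(unname(n2["g", "m"]), 2 * unname(n1["g", "m"]))
})

test_that("compare_nms contract: ties, extremes, planted recovery", {
  nms <- matrix(c(rep(1, 10), rep(1, 10)), 20, 1,
                dimnames = list(sprintf("g%d", 1:20), "F"))
  res <- compare_nms(nms, sprintf("g%d", 1:10), sprintf("g%d", 11:20), "F")
  expect_equal(res$p_value, 1)
  expect_equal(res$effect, 0)

  nms2 <- matrix(c(11:20, 1:10), 20, 1,
                 dimnames = list(sprintf("g%d", 1:20), "F"))
  res2 <- compare_nms(nms2, sprintf("g%d", 1:10), sprintf("g%d", 11:20), "F")
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_gt(res2$effect, 0)

  expect_error(compare_nms(nms, sprintf("g%d", 1:10), sprintf("g%d", 8:20),
                           "F"), class = "ifnregnet_input_error")
  expect_error(compare_nms(nms, sprintf("g%d", 1:4), sprintf("g%d", 11:20),
                           "F"), class = "ifnregnet_input_error")
})
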
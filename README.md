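# ifnregnet

Endothelial cells in injured and failing hearts can adopt an
interferon-responsive, immune-regulatory state marked by broad induction of
interferon-stimulated genes (ISGs). Establishing that claim computationally
takes several bespoke analyses that standard toolkits do not provide in one
place: scoring an ISG program per cell against an expression-matched
background, testing differential expression and cluster-composition shifts
between conditions, scanning accessible chromatin for transcription-factor
(TF) binding motifs at an exactly calibrated p-value threshold, linking
motif content to genes through a Normalized Motif Score, and asking which
TF families co-occur in the same peaks. `ifnregnet` implements that
pipeline as a tested R package for computational biologists who want each
step reproducible and checkable at desk scale, with a synthetic-data module
that plants known signal so every stage can be validated end to end.

## The statistics at the core

**ISG module score.** For a gene set *S* (default size 96) each cell *c*
receives

    score(c) = mean_{g in S} x_gc − mean_{b in B} x_bc

where `x` is log-normalized expression and *B* is a random background pool,
10 background genes per set gene, drawn from the same equal-frequency
mean-expression bin (24 bins). Scores are z-transformed across cells, and
groups are compared with Wilcoxon tests.

**Marker detection.** Genes expressed in ≥ 1% of either group with
|log2 fold change| ≥ 0.25 are tested with a two-sided Wilcoxon rank-sum
test (normal approximation, tie-corrected); Benjamini–Hochberg adjustment
spans the whole gene universe. QC uses the cutoffs: UMI in [500, 25000],
mitochondrial fraction ≤ 0.5%, doublet score ≤ 0.25%; snATAC nuclei need
FRiP ≥ 15% and peak-region fragments in [30 K, 1500 K].

**Composition test.** Per cluster,
`log2FD = log2((prop1 + ε)/(prop2 + ε))` with ε = 1/(total cells); the
two-sided p-value comes from permuting condition labels over cells.

**Motif scanning.** Each PWM becomes a log2-odds matrix
`log2((p + 0.001·bg)/(1.001·bg))`; the exact distribution of the window
score under the i.i.d. background is computed by convolving
integer-discretized per-position scores (1000 units per log2 unit), and a
window on either strand is a hit when its score reaches the smallest
threshold with tail probability ≤ 1e-4.

**Normalized Motif Score.** With peaks assigned to a gene's body or its
2-kb upstream promoter,

    NMS(g, T) = Σ_i  a_i · m_i(T) / L_i

over assigned peaks *i*, where `a_i` is mean accessibility in a chosen cell
population, `m_i(T)` the motif hit count of TF (or family) *T*, and `L_i`
the peak length in kb. Gene sets are compared by Mann–Whitney U.

**TF-family co-occurrence.** Pearson correlation of family-level hit
counts across peaks defines a weighted network; non-positive edges are
dropped and communities come from Newman's leading-eigenvector spectral
method with a deterministic sign convention. Partitions are compared with
the adjusted Rand index.

## Worked example

```r
library(ifnregnet)

cfg <- simulation_config(n_genes = 800, n_cells = 1000, isg_shift = 0.5,
                         seed = 17)
sim  <- simulate_expression(cfg)
norm <- normalize_log(qc_filter_cells(sim$matrix)$matrix)
sc   <- module_score(norm, sim$truth$isg_gene_ids, seed = 17)
md   <- qc_filter_cells(sim$matrix)$matrix$metadata
tapply(sc$z, md$cluster, mean)
#>  cluster_1  cluster_2  cluster_3  cluster_4  cluster_5
#>  1.6427596 -0.4610647 -0.4799774 -0.4804652 -0.4383971
high <- sc$cell_id[md$cluster == sim$truth$isg_high_cluster]
compare_scores(sc, high, setdiff(sc$cell_id, high))$p_value
#> [1] 1.703258e-107
```

`cluster_1` is the planted ISG-high cluster: its mean z-score (+1.64)
stands far above every other cluster and the rank-sum test against the
remaining cells is decisive. The same pattern on real data is what
identifies an IFN-responsive endothelial subpopulation.

The regulatory side runs the same way from planted inputs:

```r
reg  <- simulate_regulatory(simulation_config(genome_n_seqs = 4,
                                              seq_len = 60000,
                                              n_target_genes = 25,
                                              seed = 17))
hits <- scan_peaks(reg$genome, reg$peaks, reg$motifs)      # p <= 1e-4
nms  <- compute_nms(hits, reg$peaks, assign_peaks(reg$peaks, reg$genes),
                    reg$access, "popA", level = "family",
                    family_map = reg$family_map)
str(compare_nms(nms, reg$truth$target_gene_ids,
                setdiff(rownames(nms), reg$truth$target_gene_ids), "FAM1"))
#> List of 3
#>  $ statistic: num 676
#>  $ p_value  : num 0.0155
#>  $ effect   : num 10.1
```

Target genes (3x planted motif density, doubled accessibility) score
higher NMS than background genes — here family FAM1 separates at
p ≈ 0.016 with a median NMS difference of 10.1 for this seed — the
synthetic analogue of elevated IRF/BATF/STAT motif scores at IFN-EC
genes.

A full orchestrated run (simulate → qc → score → markers → composition →
scan → nms → network, with a manifest of parameter snapshots and output
hashes) is:

```r
run_pipeline(demo_config(out_dir = "demo_run", seed = 1))
```

or from the shell: `Rscript inst/cli/ifnregnet.R demo --outdir demo_run
--seed 1`.

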
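---
title: "Methods: models, parameters and design choices in ifnregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ifnregnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ifnregnet` links a single-cell interferon-stimulated-gene (ISG) program
to accessible chromatin: module scoring, differential statistics, exact
p-value-calibrated PWM scanning, the Normalized Motif Score (NMS) and
TF-family co-occurrence networks. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic
generator does and does not establish.

## ISG module scoring

The score of gene set $S$ in cell $c$ is
$\bar{x}_{S,c} - \bar{x}_{B,c}$ on log-normalized expression
($\ln(1 + 10^4\,\mathrm{count}/\mathrm{total})$), where the background
$B$ holds `pool_factor = 10` genes per set gene drawn uniformly without
replacement from the set gene's mean-expression bin, set genes excluded.
With duplicates across set genes allowed, $|B|$ is exactly ten times the
set size. `n_bins = 24` equal-frequency bins is the common default for
this scoring family; the underlying method description says only
"similar expression levels", so the bin count is exposed as a parameter.
Binning uses a canonical order (mean, then gene id) and candidates are
sorted before sampling, so scores are invariant to gene and cell order
and exactly reproducible from the recorded provenance (seed, bin count,
background ids). If a bin offers fewer candidates than `pool_factor` the
draw falls back to sampling with replacement, with a warning.

Raw scores are z-transformed with the population SD; a zero-SD vector
yields all-zero z with a warning. Group comparisons default to the
unpaired two-sided Wilcoxon rank-sum test. The source method names a
signed-rank test for what is an unpaired comparison of patient versus
control cells; a signed-rank test requires matched pairs, so the package
defaults to rank-sum and exposes `paired = TRUE` for genuinely paired
designs. This discrepancy is deliberate and logged here.

## QC, markers, composition

QC cutoffs are fixed by the protocol being reproduced: UMI in
$[500, 25000]$, mitochondrial fraction $\le 0.005$, doublet score
$\le 0.0025$ (the quoted "0.5%" and "0.25%" read as fractions of their
scales; both configurable since the doublet-score scale is not
specified), and for snATAC nuclei FRiP $\ge 0.15$ with peak-region
fragments in $[3\times10^4, 1.5\times10^6]$. Removal counts are
attributed to the first failing rule in a fixed order so reports
reconcile exactly.

Marker detection tests genes expressed in $\ge$ `min_pct = 0.01` of
either group with $|\log_2 FC| \ge$ `logfc_threshold = 0.25`
(`0.2` when reproducing the DEG threshold), using the tie-corrected
normal approximation to the Wilcoxon rank-sum statistic — the standard
choice at hundreds of cells; tests validate it against an exhaustive
permutation oracle at $n = 10$ per group. The fold change is
$\log_2\!\big(\frac{\overline{\mathrm{expm1}(x_1)} + 1}
{\overline{\mathrm{expm1}(x_2)} + 1}\big)$.
**Adjustment spans the whole gene universe** (untested genes enter at
$p = 1$): adjusting only the survivors of the effect-size filter is
anti-conservative by construction — the filter selects null genes with
extreme observed effects — and measurably fails to control the false
discovery proportion at the 1% level; correcting over all genes matches
the reference toolkit's adjusted p-values and restores control. The
normalization itself is plain library-size log scaling: the original
workflow's variance-stabilizing regression is a large external method,
and every downstream test here is rank-based.

The cluster-composition method is unspecified in the source beyond the
reported statistic ("P < 0.001, log fold difference > 1"), so the package
adopts a label-permutation test: per cluster,
$\log_2\frac{p_1 + \varepsilon}{p_2 + \varepsilon}$ with
$\varepsilon = 1/N$ cells, null built by shuffling condition labels,
two-sided $p = (1 + \#\{|T^{perm}| \ge |T^{obs}|\})/(1 + n_{perm})$.
It is distribution-free, matches the reported statistic's form, and is
calibrated (type-I $\approx 0.05$) in the acceptance suite. Log base 2 is
assumed for "log fold difference" and configurable in interpretation.

## Motif scanning with exact thresholds

Log-odds follow the FIMO scoring model with pseudocount
$0.001 \cdot bg(b)$; the background defaults to uniform 0-order
(FIMO's default; the source does not state otherwise) and can be
estimated from peak sequences. Per-position scores are discretized at
1000 integer units per log2 unit and convolved position-wise to get the
exact window-score distribution under the background; the threshold is
the smallest score with tail mass $\le 10^{-4}$ (the quoted cutoff).
Discretization error is bounded by $L/1000$ log2 units for an $L$-bp
motif, far below the $10^{-4}$ regime for motifs up to 25 bp; supports
above $5\times10^6$ values raise a resolution error suggesting a lower
granularity. Scanning uses the same discretized matrices as the
threshold, so threshold and scanner are consistent to the unit, and the
acceptance suite shows exact agreement with 4^L enumeration. Both
strands are scanned (reverse strand via the reverse-complemented
matrix), windows containing N never match, and overlapping qualifying
windows each count (FIMO behavior; no masking). A consequence worth
knowing: motifs shorter than 7 bp cannot attain $p \le 10^{-4}$ (the
single best window already has $4^{-6} > 10^{-4}$) and yield zero hits,
exactly as FIMO's p-value filter would.

## Peak assignment and NMS

Peaks are intervals in 0-based half-open coordinates throughout. A peak
is assigned to every gene whose body or 2-kb strand-aware promoter
(upstream of the TSS, clipped at zero) it intersects — no nearest-gene
exclusivity, matching the gene-activity convention of summing fragments
over body + promoter. The NMS reading adopted is
$\mathrm{NMS}(g,T) = \sum_i a_i\, m_i(T) / L_i$ with $a_i$ the peak's
mean accessibility in a chosen population, $m_i$ its hit count and
$L_i$ its length in kb: the published formula text is garbled, and this
is the only weighted summation of motif counts using all three named
quantities. Two properties are asserted in tests to prevent silent
redefinition: NMS is linear in each $a_i$ and $m_i$, and per-peak length
normalization means splitting a peak into halves does *not* preserve the
score. Family-level NMS is computed by summing member-TF NMS columns, so
the family/member identity holds exactly in floating point. Which
population supplies $a_i$ is a required argument (the source does not
say which it used); comparisons between gene sets use Mann–Whitney U
with a median-difference effect.

## Co-occurrence networks and spectral communities

Family count vectors are motif counts summed over family members; the
network edge between two families is the Pearson correlation of their
counts across the chosen peaks. Families with fewer than `min_nonzero =
5` nonzero counts or zero variance are dropped with a warning.
Correlations at or below `weight_floor = 0` are removed before community
detection because modularity is ill-defined for negative weights (the
source is silent on thresholding; the floor is exposed). Communities
come from Newman's leading-eigenvector method — the canonical spectral
community algorithm in the toolkit family the source cites — implemented
in-package by recursive bisection on the sign of the leading eigenvector
of the generalized modularity matrix, stopping when no split increases
modularity. Determinism: the eigenvector sign is fixed by making its
largest-magnitude entry positive, and zero-degree nodes are fixed as
singletons (so adding an isolated node adds exactly one community). The
implementation is validated against igraph's leading-eigenvector
clustering on planted two-block graphs. Whether the source correlated at
family level directly or aggregated motif-level correlations is
ambiguous; family-level (as quoted) is implemented.

## The synthetic world

The generator's defaults are the stated experiment at desk scale: 2,000
genes x 2,000 cells in 5 clusters across two conditions; a 96-gene ISG
panel raised by `isg_shift = 0.5` (natural log) in one cluster; 100 DEGs
at fold 2; negative-binomial counts (dispersion 0.5, i.e. size 2) with
log-normal gene abundances and mean depth 5,000 UMI; an 8%-vs-2% planted
composition shift (log2 fold difference 2) in the last cluster; 5% of
cells planted above the mito/doublet QC cutoffs. ISG and DEG genes are
drawn from genes above the 30th abundance percentile — curated panels
and reported DEGs are detectably expressed genes; planting them in the
unexpressed tail would test nothing the thresholds could see.

The regulatory side tiles genes with strand onto i.i.d. uniform
sequences, places 1–5 non-overlapping 200–500-bp peaks per gene inside
body + promoter, and plants sharp-consensus (0.85/0.05) 8-bp PWMs by
substitution at non-overlapping offsets, so coordinates never shift and
every planted occurrence is recoverable. `plant_rate = 1` expected
occurrence per background peak; target-gene peaks get
`target_density_multiplier = 3` times that, and their accessibility is
doubled in the designated population. Co-occurrence structure: target
peaks are co-planted (probability 0.9) by the target family blocks;
background peaks by a cross-cutting family partition — emulating a
different regulatory grammar away from the target genes, which is what
makes block communities recoverable at target peaks and genuinely
dissolve elsewhere. Planting events are rate-normalized by expected
motifs per event, so a multiplier of 1 equalizes hit rates exactly
(the null configuration).

One global seed drives everything through per-stage derived substreams
(Mersenne-Twister; the derivation is a documented integer hash), giving
bit-identical outputs across runs.

What a green test does **not** establish: the generator has no batch
effects, no ambient RNA, no doublet structure beyond a scalar score, no
read-level error, first-order-independent background sequence, and
planted motifs are exact consensus strings — real CisBP motifs are
softer and real peaks have higher-order sequence composition. Green
means the algorithms do what their definitions say and recover signal
whose form they assume, not that the biological effect sizes are
realistic.

## Known limitations

- The Wilcoxon normal approximation is unreliable below ~10 cells per
  group; tests there should use exact methods.
- NMS has no distance decay: a peak 1 bp and 1,999 bp upstream weigh
  equally, and a peak overlapping two genes counts fully for both.
- Modularity-based communities inherit the resolution limit; very small
  blocks in large networks may not separate.
- The composition test permutes cells as exchangeable units; it does not
  model per-sample (donor-level) correlation.
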
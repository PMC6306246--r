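---
title: "Methods: compartment-aware comparison of single-nucleus and single-cell RNA-seq"
author: "compartseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-aware comparison of single-nucleus and single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartseq)
```

## The problem

A nucleus contains only part of a cell's mRNA: unspliced transcripts, plus
a set of mature transcripts that are preferentially retained in the
nucleus. Single-nucleus RNA-seq therefore under-samples cytoplasmic
messages, and any comparison with whole-cell data has to model the
compartment difference explicitly. The key observation the pipeline is
built on is that intronic sequencing reads can essentially only come from
unspliced, nucleus-resident transcripts, while exonic reads come from both
compartments. Quantifying the two read classes separately gives (i) more
statistical power for cell-type discrimination in nuclei and (ii) a handle
on the *nuclear fraction* of a cell's transcriptome — per cell type
(`F_t`) and per gene (`pi_g`).

## Expression quantification

Expression is counted per gene per sample in two layers, exonic and
intronic, with gene rows and sample columns everywhere. The working unit
is CPM — counts per million of exonic plus intronic reads — and
log2(CPM + 1) for anything variance-based. `compute_cpm(reads = "exonic")`
normalizes within the exonic layer (each sample sums to 10^6). The
nuclear-fraction estimators instead use an *exonic-over-total* view
(exonic counts per million of the whole library, `cpm_exonic_of_total()`,
internal): the numerator is restricted to exonic reads but the sequencing
depth is the full library. This matters: every transcript carries its
exons, so per-transcript exonic yield is comparable between a nucleus and
a whole cell only when both are normalized by total sequencing effort.
Normalizing by exonic totals alone would deflate the nucleus's denominator
by its (large) intronic share and bias every ratio estimator by an
intron-share-dependent factor. FPKM is offered for absolute-level
summaries and is computed from exonic reads only, because intron retention
varies too much across genes for intron-inclusive effective lengths to be
meaningful.

QC filters are strict inequalities with configurable thresholds; the
defaults (nuclei: >500,000 mapped reads, >75% aligned, >50% unique; cells:
>200,000 mapped reads, >1,000 genes detected) match the library-selection
rules the pipeline was designed around.

## Dropout model and weights

Gene dropout — a truly expressed gene observed at zero — is modelled per
sample by a logistic curve in expected expression. For sample *s*, the
expected expression of gene *g* is the mean log2(CPM + 1) over the
sample's `k = 8` most-correlated samples, treating neighbor zeros as
missing so the expectation reflects magnitude-when-detected. A binomial
GLM of the detected/undetected indicator on this expectation gives
`p(dropout | x)`; slopes are constrained non-negative so the curve is
monotone non-increasing in expression, and degenerate samples (no zeros,
or nothing detected) are clamped to probability 0.01 / 0.99 with a
warning. This is a deliberately transparent replacement for a Bayesian
per-cell error model: downstream steps only need a calibrated
`p(dropout | expression)`.

Weights combine the dropout probability at the observed value and at the
neighborhood expectation:

`W_sg = 1 − p(x_sg) · p(x_sg) · p(x̄_g)`  (default), or
`W_sg = 1 − p(x_sg) · p(x̄_g)`  (`formula = "simple"`).

The squared form is the default; whether the squaring is intentional in
its original statement is ambiguous, so both variants are selectable and
comparable. Pairwise analyses (correlation, PCA) use the product
`W_sg · W_tg` as the per-gene weight for the sample pair *(s, t)*.

## Nucleus-cell matching

Dropout-weighted Pearson correlations are computed between every nucleus
and every cell over genes expressed in at least one nucleus and one cell.
Matching is *global greedy*: the single highest correlation in the matrix
is emitted as a pair, its row and column removed, and the process
repeated. Emitted correlations are therefore non-increasing. Ties break on
the lowest (nucleus, cell) index for determinism. The alternative reading
— best cell per nucleus in a fixed nucleus order — was rejected because
the global formulation matches "highest correlation to any nucleus".

## One clustering round

1. **Variable genes.** For each gene the dropout-weighted variance of
   log2(CPM + 1) (after winsorizing the `trim = 3` most extreme samples
   per tail, so single outliers cannot create "variability") is divided by
   a running-median mean-variance trend; this *adjusted variance* has null
   expectation 1 at every expression level. A gene is selected when the
   adjusted variance exceeds 1.25 **and** is significant at
   Benjamini-Hochberg FDR 0.05 under a chi-square reference whose degrees
   of freedom are calibrated, per expression stratum, to the robust (MAD)
   spread of the stratum's ratios. The local calibration exists because
   the variance-of-variance of near-zero-inflated genes is far wider than
   the nominal chi-square; without it, low-expression noise genes dominate
   the selection. The significance requirement is what makes selection on
   structureless data return (almost always) nothing, which is one of the
   recursion's stop criteria.
2. **Weighted PCA.** Sample-pair covariances are weighted averages over
   genes with weights `W_sg · W_tg`, rescaled so that with unit weights
   the eigenvalues equal standard PCA eigenvalues exactly (verified to
   1e-8 in the tests). Eigenvectors are scaled by the square root of their
   eigenvalues into coordinates.
3. **PC retention.** The leading run of components whose explained-variance
   proportion beats the broken-stick expectation
   `b_k = (1/p) Σ_{i=k..p} 1/i`, capped at 20. Retaining zero components is
   a stop criterion.
4. **Graph.** k-nearest-neighbor sets (Euclidean metric in the retained PC
   space; k = 15, reduced to n − 1 when n ≤ 15 samples) are compared by
   Jaccard similarity; positive similarities become edge weights of an
   undirected sample graph. The Euclidean metric is the conventional
   choice; nothing downstream depends on it beyond neighbor ranking.
5. **Louvain + modularity gate.** Louvain community detection (seeded for
   determinism) proposes a split with modularity `Q_obs`. The split is
   accepted only if `Q_obs` exceeds the expected modularity of an
   Erdős–Rényi graph with the same number of nodes and the observed edge
   density. That expectation is the larger of two closed-form
   approximations of a random graph's maximal modularity — the fluctuation
   estimate `(1 − 2/√n) (2/(np))^{2/3}` and the spin-glass ground-state
   estimate `0.97/√(np)` — because either alone sits too close to what a
   good heuristic actually achieves on random graphs: taking the max keeps
   the false-split rate on pure-noise graphs at or below 5% (a calibration
   the test suite checks directly on G(100, 0.1) over 50 seeds). A Monte
   Carlo estimator (mean Louvain modularity over simulated G(n, p)
   graphs) is available as an alternative `method`.
6. **Markers and merging.** For every accepted cluster pair, marker genes
   must satisfy Welch-t + BH FDR < 0.05 on log2(CPM + 1) *and* either
   binary detection (CPM > 1 in >50% of one cluster, <10% of the other) or
   a >100-fold mean-CPM difference. Pairs in which either side lacks a
   marker merge, closest pair (centroid correlation) first. The Welch test
   replaces a moderated-t fit; it is exact enough at the cluster sizes the
   pipeline enforces (≥3) and keeps the dependency surface small.

Recursion proceeds into each accepted cluster with deterministically
derived child seeds and stops on any of: fewer than six samples, no
variable genes, no retained PCs, no significant split. Louvain clusters
smaller than 3 are absorbed into the most-correlated sibling before marker
checks.

## Bootstrap consensus

The full recursion is repeated (default 100 times; 20 in the scaled-down
test configuration) on random 80% subsets. `M[s, t]` is the fraction of
iterations *in which both s and t were drawn* that co-clustered them —
conditioning on joint inclusion keeps entries unbiased probabilities
(unconditional proportions would be deflated by the ~64% co-sampling
rate). Pairs never co-sampled are NA and are mean-imputed only for tree
building. Average-linkage hierarchical clustering of `1 − M` is cut at
heights 0.01–0.99 in steps of 0.01; the chosen height is the one whose
cluster count is nearest the median per-iteration count, smallest height
on ties — a static-height scan that preserves the selection logic of a
hybrid dynamic cut without its library-specific heuristics. Cohesion
(mean within-cluster co-clustering), separation (cohesion minus maximum
between-cluster co-clustering) and their per-sample analogues quantify
robustness; a final merge removes pairs with separation < 0.25 or missing
markers, recomputing markers on the full data (per-iteration marker sets
would be noisier and order-dependent).

## Beta marker score and cluster matching

For per-cluster detection proportions (CPM > 1) `x_1..x_n`,
`beta = Σ_ij (x_i − x_j)² / (Σ_ij |x_i − x_j| + ε)` with ε = 1e-6 by
default (configurable; the exact 0 and 1 endpoints are attained at ε = 0).
Cluster dendrograms use mean log expression of the top 1200 beta genes
and complete linkage on a correlation distance, `(1 − ρ)/2` by default —
the printed form of that distance is typographically ambiguous, so `1 − ρ`
is selectable; the choice only rescales heights and cannot reorder
topologies. Cross-dataset matching filters to genes with beta > 0.3 in
both datasets, majority-expressed in between 1 and 5 clusters, weights
each gene by the *smaller* of its two beta scores (so a gene
uninformative in either dataset contributes nothing), and reports
reciprocal best matches of the beta-weighted correlation matrix.

## Nuclear fraction estimation

Let s_g be the intronic share of reads from an unspliced transcript of
gene g, and r_g = s_g/(1 − s_g) its intron/exon read-mass ratio.

- **Intron-ratio estimator**: mean intronic read proportion of cells of a
  type divided by that of matched nuclei. Since intronic reads are
  nuclear-only, the cell's intronic share is the nucleus's share diluted
  by cytoplasmic reads, and the ratio identifies the read-level nuclear
  fraction regardless of r_g.
- **Nuclear-gene estimator**: mean cell/nucleus ratio of exonic-over-total
  expression of *Malat1*, *Meg3*, *Snhg11* (configurable symbols, exact
  matching). For a fully nuclear transcript this ratio again identifies
  the read-level nuclear fraction.

Both carry delta-method standard deviations
(`var(A/B) ≈ (A/B)²(var(A)/A² + var(B)/B²)` on the standard errors of the
means), and estimates are capped at 1. Per-sample intron proportions are
averaged within type before ratioing (matching per-sample summaries)
rather than pooling reads. Per-gene fractions are
`min(1, (mean nuclear CPM / mean cell CPM) × F_t)` per type, averaged
across types with the gene's mean log2(CPM + 1) in cells as weight, over
genes detected in >50% of samples of at least one cluster; types with
zero cell expression for a gene are skipped. The FISH estimator is the
free-intercept least-squares slope of nuclear on soma spot counts
(binomial thinning gives slope = thinning probability; fixing the
intercept is unnecessary for identification). The morphology estimator is
`(nucleus area / soma area)^{3/2}`, valid on average for approximately
symmetric somata only.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. Its
model: each gene in each type has an expected exonic read mass `mu_gt`
(lognormal baseline, hierarchically perturbed along a binary type tree,
with planted binary marker genes per type); a transcript-level nuclear
fraction `pi_g` (Beta(2, 2) by default, truncated to (0, 1]); and an
intron/exon read-mass ratio `r_g` (lognormal, median 0.8), coupled to
`pi_g` through a Gaussian copula (ρ = 0.5) because nucleus-enriched genes
tend to be long. Cells carry both compartments — exonic mass `mu_gt`,
intronic mass `mu_gt · pi_gt · r_g` — while nuclei carry only the nuclear
compartment (`mu_gt · pi_gt` exonic, same intronic). Counts are negative
binomial (dispersion 10; Poisson and deterministic-expected variants
available) with per-sample lognormal library sizes (median 5 × 10^5),
followed by Bernoulli dropout with logistic probability in log2 expected
CPM (midpoint 1.5, slope 1 — a 50% dropout chance at expected CPM ≈ 2,
vanishing for well-expressed genes; `midpoint = -Inf` disables dropout).

The configured `nuclear_fraction_per_type` is defined at the *read* level
— the expected fraction of a cell's reads deriving from nuclear
transcripts — and per-type `pi_gt` are rescaled by root finding so the
realized read-level fraction matches it exactly. This is the quantity
both type-level estimators identify, which is what makes recovery tests
well-posed; the per-gene estimator in turn identifies transcript-level
`pi_g` exactly in expectation under this read model. Three planted
"nuclear genes" (default symbols Malat1, Meg3, Snhg11) are held at
`pi = 1` and 1–2% of library mass each, mirroring their real-world role
as highly expressed nuclear transcripts. Per-type nuclear-fraction
defaults (0.35, configurable per type) sit inside the 0.2–0.5 range
typical of neurons.

What the generator does *not* emulate: within-type continuous
heterogeneity (type profiles are exact, so within-type data are pure
noise), batch or amplification effects, gene-gene correlation beyond the
type structure, ambient RNA, doublets, and read-level artifacts (no
FASTQ, alignment, or spike-ins). Passing recovery tests therefore
demonstrates correctness of the estimators and of the clustering logic
under the stated noise model — not robustness to every artifact of real
libraries.

## Numerical choices and degenerate inputs

- All-zero samples: flagged with a warning, CPM defined as 0 (robustness
  on subsamples beats erroring).
- Zero weighted variance in a weighted correlation: NA, never a crash.
- Greedy matching, Louvain and merge orders: deterministic (fixed seeds,
  lexicographic tie-breaks); recursion and bootstrap seeds derive from the
  parent seed by a fixed integer map below 2^31.
- Calibration root finding: bracketed on (1e-9, 1e6) with tolerance 1e-10,
  saturating (rather than failing) when fixed purely nuclear genes alone
  exceed the requested fraction.
- Winsorization trim scales down on small subsets (`floor(n/15)`, max 3)
  so tiny recursion leaves are not over-trimmed.
- The noise-model k is reduced to n − 1 on subsets smaller than k + 1.

## Problem sizes used in the tests

The suite exercises the pipeline at desk scale, chosen to keep the
complete run in the low minutes while leaving comfortable statistical
margins: 3 planted types × 50 samples × 2,000 genes for clustering
recovery; 20 bootstrap iterations for consensus; 100 samples per
compartment per type for nuclear-fraction recovery; 50 seeds of
G(100, 0.1) for gate calibration; 300 samples × 1,000 genes for
variable-gene operating characteristics.

## Known limitations

- The modularity null approximations are closed-form stand-ins for the
  original (unreprinted) equations; they are validated against their
  stated purpose (false-split control) rather than against a source text.
- The adjusted-variance definition is this package's own (the original
  delegates to an external error model without printing a formula); its
  operating characteristics are documented by the tests, not inherited.
- The Welch t replaces moderated-t throughout; at very small cluster
  sizes (3–5 samples) it is conservative.
- Nuclear-fraction estimates inherit the assumption that *all* intronic
  reads are nuclear; intron-retaining cytoplasmic transcripts would bias
  both type-level estimators upward.
- The morphology estimator assumes cross-sections reflect symmetric 3-D
  shapes; individual cells can be badly estimated even when the average
  is unbiased.
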
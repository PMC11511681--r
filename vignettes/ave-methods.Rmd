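---
title: "Methods: AVE identity and migration phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AVE identity and migration phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the statistical models and algorithmic choices
behind `aveflow`, the assumptions they make, and what the synthetic-data
validation does and does not demonstrate about real data.

## The biological problem

Between 5.5 and 6.5 days post coitum the anterior visceral endoderm (AVE)
of the mouse embryo migrates from the distal tip towards the prospective
anterior side, setting up the anterior-posterior axis. Characterising this
population means (i) resolving it transcriptionally against the adjacent
embryonic and extra-embryonic visceral endoderm, epiblast and
extra-embryonic ectoderm, with principled control over the number of
clusters; (ii) ordering AVE and emVE cells along a continuous
spatial/developmental axis; (iii) asking which signals these cells can
send and receive; and (iv) quantifying the *motion* of the population in
live imaging, robustly enough to compare genotypes.

## Quality control and normalization

Cells are retained when they simultaneously satisfy five criteria: more
than 3,000 genes above 10 reads per million, log10 total reads above 4,
mapped fraction above 0.5, mitochondrial fraction below 0.1 and spike-in
fraction below 0.3. These defaults suit deeply sequenced plate-based
(Smart-seq2-style) libraries; droplet data would need different values.
`filter_cells()` reports per-criterion failure counts because a failing
cell often violates several criteria at once.

Size factors come from a pooled-deconvolution estimator: cells are
ordered on a ring by library size, counts are summed over sliding pools
of several sizes (21, 15, 9 by default), each pooled profile is compared
to the average composition by a median ratio, and the resulting linear
system (pool totals = sums of member factors) is solved by ridge-damped
least squares, anchored so factors average to the mean library size and
rescaled to mean 1. Pooling suppresses per-gene zero inflation, which is
what makes deconvolution more robust to composition bias than plain
library-size scaling; a `method = "library"` fallback exists for small or
degenerate inputs. Several pool sizes are used because a single pool size
produces a circulant design matrix that can be rank-deficient. Normalised
values are `ln(count / size_factor + 1)`.

Highly variable genes are ranked by within-bin dispersion: the de-logged
per-gene dispersion (variance/mean) is standardised inside 20
equal-occupancy bins of the mean, genes with `log1p(mean)` above
`max_mean = 10` are excluded, and the top 3,000 (default) are kept. The
within-bin standardisation is robust (median and MAD rather than mean and
standard deviation): a bin can legitimately contain several genuine HVGs,
and a mean/sd z-score would let them mask each other while promoting mild
outliers from tight bins. Bin count is reduced automatically when few
genes are available, since a z-score inside a near-empty bin is
meaningless.

## Clustering with Variation-of-Information model selection

Cells are clustered hierarchically (average linkage) on the Spearman
correlation distance `d = (1 - rho)/2`, which is insensitive to monotone
distortions of expression. The dendrogram is cut with a simplified hybrid
rule indexed by a `deepsplit` parameter 0-4: static cuts at the 0.99,
0.95, 0.90, 0.80 and 0.70 quantiles of the merge heights, followed by
reassignment of clusters smaller than `min_size = 10` to the nearest
retained cluster by average distance. What matters for the procedure is
not the specific cutter but that deepsplit indexes a family of
increasingly aggressive cuts that the model-selection scan can traverse.

The number of clusters is chosen by robustness, not by an internal index:
for each deepsplit, the full-feature partition is compared (average
Variation of Information, natural log) against partitions recomputed on
50 random half-gene subsamples. VI is a true metric on partitions, which
the test suite verifies against a brute-force entropy oracle. Stable
partitions give a low average VI; once cuts start shattering real
clusters the curve jumps. The chosen deepsplit is `argmax_d
avg_VI(d+1) - avg_VI(d)` — the point just before the largest jump — with
ties resolved towards the smallest deepsplit, so a totally flat curve
yields the most conservative cut. The log base is irrelevant to the
argmax.

Markers are computed per pair of clusters with a two-sided Wilcoxon
rank-sum test (exact null distribution for small tie-free groups, normal
approximation with tie and continuity correction otherwise — validated
against full enumeration), BH-adjusted within each comparison. A gene is
a marker of cluster `c` when at least one comparison against another
cluster has log2 fold change above 1 and adjusted p below 0.1; genes are
ranked by the average `-log10` adjusted p over all of the cluster's
pairwise comparisons. Under this rule a gene may mark several clusters,
which is deliberate: shared markers are informative about related
populations. The log2 fold change is computed on de-logged mean
expression with a 1e-9 pseudocount.

## Sub-clustering

Sub-structure inside a cluster is searched with Leiden community
detection (modularity objective) on a kNN graph over the first 10
principal components of the top 2,000 HVGs, across a grid of k in
{15, 20, 25, 30, 35} and resolution 0.1-1.0 in steps of 0.1. Each grid
point's robustness is again the average VI against half-gene
re-clusterings. To prevent overfitting, clusters are required to have at
least two *specific* markers — genes with mean lognorm expression above
0.01 in the cluster that are significantly upregulated (adjusted p < 0.1,
positive fold change) in **every** pairwise comparison; unsupported
clusters are merged into the Euclidean-nearest cluster centroid and the
rule is re-applied until it holds (the cluster count strictly decreases,
so this terminates). The selected partition is the post-merge partition
with more than one cluster that has the lowest average VI, ties towards
fewer clusters; when none survives, the data are declared homogeneous.
The specific-marker thresholds are inherited from the marker stage, as
the defining publication style for this procedure leaves them implicit.

For stages where the unsupervised grid finds a single cluster,
`signature_split()` runs community detection on a kNN graph built from a
small externally derived gene signature only (e.g. the top 10 up- and
10 down-regulated genes between subclusters found at a later stage),
which can resolve weak splits that are invisible against the full
transcriptome background.

## Diffusion pseudotime and trend grouping

The diffusion map uses a Gaussian kernel with per-cell adaptive bandwidth
(the distance to the ceiling(k/2)-th neighbour, k = 15), a union
symmetrisation with self-affinity, and density normalisation with
alpha = 1 to cancel sampling-density effects. The transition operator is
analysed through its symmetric conjugate `S`; diffusion components are
ordered by eigenvalue, with DC1 the trivial stationary component. The
pseudotime of a cell is its distance to the root in the accumulated
operator `M = (I - (S - phi1 phi1'))^-1 - I`, evaluated in the eigenbasis
as `sqrt(sum_i (lambda_i/(1-lambda_i))^2 (phi_i(x) - phi_i(root))^2)`;
the test suite checks this against the explicit matrix inversion on a
small chain graph. The root is the cell at the minimum or maximum of DC2
— a stage-dependent biological choice, so the package refuses a default
and requires `root_dc2 = "min"` or `"max"` (or an explicit cell). Only
the single-branch pseudotime coordinate is implemented, since the
coordinate is used as a 1-D spatial axis.

The kNN graph accepts Euclidean or Spearman distance over the PCs.
Recovery tests use the Euclidean graph: on a synthetic 1-D gradient only
one principal component carries signal, and a rank correlation across 10
PC coordinates (9 of them noise) is information-limited at any
sequencing depth, for this package's implementation and for an
independent one alike — the limitation belongs to the metric under these
conditions, not to the diffusion machinery. On real data, where several
PCs carry correlated structure, the two metrics behave far more
similarly; the Spearman option remains available and contract-tested.

Differential expression along pseudotime fits each gene with a natural
cubic spline (4 effective degrees of freedom) and tests it against an
intercept-only model by an F-test, BH-corrected (FDR < 0.01 by default);
genes detected in fewer than 10 cells are excluded. Significant genes'
fitted trends are standardised and clustered with the same VI-guided
hierarchical machinery (genes as elements, minimum cluster size 50,
robustness by resampling 70% of *cells* 50 times); each trend cluster is
labelled `high_in_AVE` when its mean trend decreases along pseudotime
(the root sits in the AVE) and `low_in_AVE` otherwise.

## Isoform differential expression

Transcript-level (TPM-like) values are compared between two clusters per
gene: genes with more than 80% of their counts on a single isoform are
removed, the remaining genes get an isoforms-by-clusters table of average
normalised expression, and a Pearson chi-squared statistic without
continuity correction is computed with BH correction across genes. The
table entries are means rather than integer counts — this follows the
established practice for this comparison; entries are clipped below at
1e-6 so expected counts never vanish. Calibration on null tables with
realistic count scales is part of the acceptance checks. Means enter on
the linear (non-log) TPM scale by default; whether to log-transform first
is genuinely underdetermined, and the linear scale was chosen because the
chi-squared machinery assumes additive composition.

## Cell-cell communication

For each node (cell type) and gene, `phi` is the expressing fraction
(values below 0.1 are set to 0 — fractions that small are
indistinguishable from ambient noise) and `p` is the mean of non-zero
lognorm values divided by the maximum of those means across nodes. Genes
detected in fewer than 10 cells or with non-zero mean below 1 are removed
first, over the full selected-cell set (before node splitting, so the
filter is identical for every node). The weight of ligand-receptor pair
alpha from node i to node j is `w_ij = (phi_i^lig phi_j^rec)(p_i^lig
p_j^rec)`; complexes multiply member genes' phi and p. Weights below the
50th percentile of all weights pooled across all LRPs are zeroed (zeros
included in the pool by default; a flag excludes them) and all-zero LRPs
are dropped. Extra literature-derived pairs enter through the same TSV
schema rather than being hard-coded.

## Bootstrap PCA loading significance

For a pathway's genes (mean lognorm expression above 0.5), PCA is run
over cells and each loading of the first three components receives a
p-value: the fraction of 1,000 bootstrap cell-resamples in which the
loading's sign, after aligning each replicate component to the
full-sample component (flipping when the loading dot product is
negative, which handles axis reflections), differs from the full-sample
sign. A gene is significant when any of its first three loadings has
p < 0.01. One subtlety the validation respects: a gene whose loading is
*exactly* zero never registers an inversion, and a gene with a small
finite-sample correlation to the leading axis inverts *less* than half
the time; the null fixture therefore uses noise orthogonalised against
the signal with a small random admixture, for which inversion fractions
concentrate around 0.5.

## Proteomics and phosphoproteomics

Peptide counts are summed per protein, log2-transformed, and normalised
by pairwise cyclic loess (span 0.7). Passes are capped at 3 with an
early-stop tolerance of 1e-6: cyclic loess is not a projection, and
iterating it many more times progressively absorbs genuine differential
signal rather than technical bias, while 1-3 passes preserve planted
fold changes (the test suite checks recovery at this setting).
Technical runs are averaged per sample (NA runs dropped), and differential
abundance between the embryonic and abembryonic halves uses a moderated
two-sample t-test with empirical-Bayes variance shrinkage and BH
correction — the natural choice for a 4-versus-4 technical-replicate
design, where per-protein variances are poorly estimated; Welch's t is
available as an alternative, and the replicate-mode caveat (technical
aliquots are not biological replicates) applies to any inference drawn.
A protein is called differential at |log2FC| > 1 and adjusted p < 0.1.
Kinase-substrate networks keep interactions whose substrate is
differential on the given side *and* whose phosphorylation site matches
exactly (case-insensitive residue letter plus position); isoform-level
site offsets are out of scope.

## Motion phenotyping

Dense optical flow is computed by quadratic polynomial expansion: each
frame neighbourhood is approximated as `f(x) ~ x'Ax + b'x + c` under a
Gaussian applicability (5x5 window, sigma 1.2), and the displacement
solves `A d = -0.5 (b2 - b1)` accumulated over a Gaussian integration
window (size 15), with 3 warping iterations per level of a 3-level
pyramid. On noise-free synthetic translations the median flow is exact to
well under a quarter pixel.

Superpixel tracking seeds ~1,000 (by default; fewer on small synthetic
frames) centroids on a regular grid of width `w_sp = sqrt(HW/n)` and
advects each per frame by the mean flow in a `w_sp`-wide window; after
each step, grid cells without any track are reseeded so cells entering
the field of view are still captured. Tracks are clamped at frame borders
rather than killed, keeping every mesh edge defined for the whole movie.
Videos are assumed registered upstream; a residual-drift check (median
global flow) warns but does not correct.

The mesh connects tracks closer than 1.2 superpixel widths at the start
frame; the strain at frame t is the mean of `|L_e(t) - L_e(0)| / L_e(0)`
over edges (a flag gives the unnormalised variant, and strain is averaged
over edges rather than per track — the edge average weights the
deformation field uniformly). This statistic is exactly zero under rigid
motion and `|s-1|` under uniform scaling, which the tests assert
analytically. Motion saliency is the Gaussian-smoothed (sigma = `w_sp`)
density of terminal track positions — forward tracking terminal positions
accumulate at motion sinks, reverse tracking at sources — max-normalised,
with the median source/sink taken over pixels above the map's 95th
percentile. Forward and reverse strain curves, truncated to the cohort's
common frame count, concatenate into the motion signature fed to a
column-centred PCA whose loadings are reported split into forward and
reverse halves.

## What the synthetic validation shows — and what it does not

The generator produces negative-binomial counts (gene baselines
log-normal, dispersion 0.4, baseline mean 5) with planted cluster
markers, monotone log-linear gradients, multinomial isoform splits,
ligand-receptor expression patterns and per-criterion QC failures; videos
are isotropic Gaussian blobs advected from a source towards a sink with
an optional logistic slow-down. Effect sizes mirror the structure of the
real system where it is known: cluster-specific programs span a few
percent of genes (40 markers per cluster out of 2,000), the pseudotime
program spans ~30% of genes (matching the fraction of
pseudotime-differential genes among HVGs in real AVE/emVE data), and the
migration cohorts use 1.5 vs 0.6 pixels/frame.

Passing these tests demonstrates that every stage recovers what it is
designed to recover under its own model assumptions, at desk scale
(hundreds of cells, 30-100 frames; the problem sizes in the acceptance
script were chosen so the whole validation runs in minutes on one CPU).
It does not demonstrate robustness to doublets, batch effects,
read-level artefacts, segmentation-free imaging noise, 3-D motion
projected to 2-D, or misregistration — none of which the generator
emulates. The QC thresholds, in particular, are only meaningful for
plate-based libraries, and the communication score inherits all caveats
of expression-proximity reasoning about signalling.

## Parameter summary

| Parameter | Default | Where |
|---|---|---|
| QC thresholds | 3000 genes / 4 log10 reads / 0.5 mapped / 0.1 mito / 0.3 spike-in | `qc_thresholds()` |
| HVGs | top 3000, max_mean 10, 20 bins | `select_hvgs()` |
| deepsplit scan | 0-4, 50 half-gene subsamples, min size 10 | `cluster_with_vi_selection()` |
| marker rule | log2FC > 1, BH p < 0.1 | `rank_markers()` |
| subcluster grid | k 15-35 step 5, r 0.1-1 step 0.1, top 2000 HVGs | `grid_subcluster()` |
| specific marker | mean > 0.01, upregulated in all comparisons, >= 2 per cluster | `count_specific_markers()` |
| diffusion | k 15, 10 PCs, adaptive bandwidth k/2, alpha 1 | `diffusion_map()` |
| trend DE | spline df 4, FDR 0.01, >= 10 cells | `trend_de()` |
| trend groups | min size 50, 70% cell subsamples, 50 times | `group_trends()` |
| communication | phi floor 0.1, 50th percentile filter, detection >= 10 cells, non-zero mean >= 1 | `summarize_nodes()`, `lrp_weights()` |
| bootstrap PCA | mean > 0.5, 1000 resamples, 3 PCs, alpha 0.01 | `pathway_pca_bootstrap()` |
| proteomics DE | loess span 0.7 (<= 3 passes), moderated t, abs(log2FC) > 1, p < 0.1 | `normalize_loess()`, `differential_proteins()` |
| flow | 5x5 expansion, sigma 1.2, window 15, 3 iterations, 3 levels | `optical_flow()` |
| tracking/mesh | 1000 superpixels, neighbour < 1.2 w_sp, saliency sigma w_sp | `track_superpixels()`, `build_mesh()`, `motion_saliency()` |
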
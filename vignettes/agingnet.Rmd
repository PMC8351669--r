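---
title: "Methods: segmented regression meets co-expression networks for aging time courses"
author: "agingnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented regression meets co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`agingnet` analyses a bulk RNA-seq aging time course in two complementary
ways — per-gene piecewise-linear trajectories over age, and weighted gene
co-expression modules associated with age and sex — and carries their
intersection to functional enrichment. This vignette documents the models,
the tunable parameters, the numerical decisions, and what the synthetic
validation data do and do not establish.

# Pre-processing

Samples are filtered on library size (default minimum 4,000,000 reads;
libraries below a few million reads give unstable per-gene estimates at
bulk depth). Genes are kept when their count strictly exceeds 10 in at
least *n* samples, with *n* the tissue's minimum age-by-sex group size:
this is the per-sample reading of the usual "count higher than 10 in at
least n samples" filter, which is robust to a single deep library; a
row-total mode (`mode = "row_total"`) is available for the alternative
reading. Counts are normalized by median-of-ratios size factors (the
geometric-mean reference excludes genes with any zero count) and
transformed with a closed-form variance-stabilizing transform for the
negative-binomial mean-dispersion relation `alpha(mu) = a1/mu + a0`, i.e.
variance `v(mu) = (1 + a1) mu + a0 mu^2`:

`vst(q) = log2( (2 a0 q + B + 2 sqrt(a0 q (a0 q + B))) / (4 a0) )`, `B = 1 + a1`,

which is the antiderivative of `1/sqrt(v)` scaled and shifted so that
large normalized counts approach `log2(q)`. The dispersion trend is fitted
by a robust (Huber) regression of method-of-moments per-gene dispersions
on `1/mean`, restricted to over-dispersed genes with mean above 1; a
negative asymptotic dispersion is clamped to 1e-8 with a warning. This is
a deliberately transparent trend fit — no gamma-GLM machinery — and the
transform is validated by its variance-flattening property (per-mean-bin
standard deviations within a factor of 2 across four orders of magnitude
of the mean), not by value-identity with any external implementation.

Outlier samples are detected on the post-filter VST matrix with a sample
network: pairwise Pearson correlation `r`, adjacency `((1 + r)/2)^2`,
connectivity `K_i`, standardized connectivity `z.K`. Samples with
`|z.K| > 2` are removed. Two open choices are made here: the deviation is
taken in absolute value (a sample can be anomalous by being *too*
connected, e.g. a duplicated library), and the network is built on the
filtered, transformed matrix rather than raw counts, where correlation is
meaningful. With fewer than 3 samples connectivity has no distribution and
the function errors; when all samples are identical, `sd(K) = 0` and
nothing is flagged.

# Segmented regression over age

Each gene's VST expression is modeled as a continuous piecewise-linear
function of age (months) with a single additive binary sex covariate
(0 = female, 1 = male):

`y = b0 + b1 t + sum_j delta_j (t - bp_j)_+ + gamma sex + eps`.

Breakpoint candidates are the interior distinct observed ages — on a
9-point grid a continuous breakpoint search adds nothing, and restricting
to the grid makes the exhaustive search exact and cheap. For each breakpoint
count `k = 0..maxK` (default 8) every admissible placement is fitted by
OLS, where admissible means every segment (samples at a breakpoint belong
to the left segment) retains at least `minPerSegment` samples (default 2;
per-tissue minimum group sizes in practice). The per-`k` minimum-RSS
placement competes across `k` by `BIC = n ln(RSS/n) + p ln(n)` with `p`
the number of fitted coefficients; constant offsets of the Gaussian
likelihood cancel in the comparison. Sex enters as a shared intercept
shift, not a sex-by-time interaction — the smallest model consistent with
"sex included as a covariate"; an interaction would double the parameter
count on a 9-point design.

Numerical decisions: the matrix fitter shares one QR decomposition per
placement across all genes, so fitting thousands of genes costs little
more than one; rank-deficient candidate designs are dropped; residuals
below `1e-12` of the baseline variation are treated as exact zeros so that
interpolation ties (several `k` reaching RSS = 0) resolve to the smallest
model; `k` is scanned in ascending order with strict BIC improvement
required, which also settles exact ties toward fewer parameters.

Segment slopes are `s_0 = b1`, `s_j = s_{j-1} + delta_j`, with p-values
from contrast t-tests on the OLS covariance; a slope is called flat when
its p-value is at or above `slopeAlpha` (default 0.1, reused as the
flatness threshold), otherwise up or down by sign.

**Adjusted R² is partial with respect to the intercept + sex baseline.**
This is the one place the package deliberately sharpens the usual
definition. The dynamic-gene cutoff is calibrated by permuting the
sample-to-age assignment while sex stays attached to its sample; under
that null a purely sex-driven gene is still perfectly explained by the
sex covariate, so a total-variance R² gives it a null score near 1 and
the pooled null quantile degenerates into a sex-effect detector. Measuring
R² relative to the `y ~ 1 + sex` baseline makes the score "variance the
time terms explain beyond sex", which is the quantity the permutation is
actually nulling. Genes with zero baseline residual variance score 0.

The cutoff itself is the inverse-ECDF (type-1) `1 - passFraction` quantile
of the pooled permuted adjusted R² values (default 10 permutations,
`passFraction = 0.01`), which guarantees the fraction of null fits
strictly above the cutoff is at most `passFraction`. A gene is top dynamic
when its adjusted R² strictly exceeds the cutoff and its smallest segment
slope p-value is below 0.1. Percentages of expressed genes are reported to
one decimal. Published per-tissue cutoffs can be supplied directly through
`pipelineParams(cutoff = ...)` instead of the permutation procedure.

Breakpoint distributions are compared across tissues by a tie-corrected
Kruskal-Wallis test followed by Dunn's pairwise z-tests; the pairwise
multiplicity adjustment defaults to Holm (the common default of the
cited implementations; configurable). Biotype composition of the dynamic
set is tested per biotype with a two-sided Fisher exact test on the
(selected vs not) x (biotype vs not) table against the reference
annotation, reporting the sample odds ratio `ad/bc` with BH adjustment
across biotypes; a chi-squared mode exists for comparison.

# Co-expression network

Gene-gene similarity is the biweight midcorrelation:
`u = (x - med(x)) / (9 MAD(x))` (MAD unscaled), weights
`(1 - u^2)^2 I(|u| < 1)`, correlation of the weighted centred profiles.
Genes with zero MAD fall back to their Pearson (mean-centred) profile for
every pair they enter ("individual" fallback); constant genes are excluded
with a warning. The signed adjacency is `((1 + r)/2)^beta`. The soft power
is chosen as the smallest with scale-free fit index at least 0.8 and
negative slope (log-frequency vs log-mean-connectivity over ~10 bins of
`log10 k`); if no power qualifies — common at small sample sizes — a
documented sample-size bracket applies (n < 20: 16, 20–29: 14, 30–39: 12,
otherwise 9), and any power can be forced.

Topological overlap is
`TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
`L = A A` (zero-diagonal A), computed as a single matrix product and
verified in tests against an O(n³) loop oracle to 1e-12. Modules come from
average-linkage clustering of `1 - TOM` with a static cut at a
`deepSplit`-dependent fraction of the maximum merge height (presets
0: 0.80 … 4: 0.99), minimum module size 50 (smaller branches fall into
`"grey"`), and iterative merging of modules whose eigengene dissimilarity
`1 - cor(ME_a, ME_b)` is below 0.15. This "tree" cut is an approximation
of the hybrid dynamic tree cut: it reproduces the branch/minimum-size/merge
semantics but not the hybrid algorithm's adaptive branch shape criteria,
so module *labels* are not expected to match the reference implementation
gene-for-gene; correctness is assessed as recovery of planted blocks
(adjusted Rand index ≥ 0.8 in the test suite). The network is built in a
single block: at the scales this package targets (up to a few thousand
genes after filtering) there is no memory reason to split, and blockwise
construction is out of scope.

Module eigengenes are the first right singular vector over samples of the
module's gene-wise z-scored matrix, unit norm, sign-oriented to correlate
non-negatively with the module's mean z-profile (so a module's "direction"
is that of its average gene). Module-trait association uses bicor with
Student-t p-values (`t = r sqrt((m-2)/(1-r^2))`) and BH FDR across modules
within each trait; modules are selected at `|r| >= 0.5` and FDR < 0.05 —
the absolute value matters, since age-anticorrelated modules are as
interesting as correlated ones. Module membership (MM, signed) and gene
significance (GS, absolute) are Pearson correlations with the eigengene
and the trait respectively; a selected module is retained when
`cor(|MM|, GS) >= 0.5` with p < 0.05, and hub genes satisfy GS > 0.2 and
MM > 0.8 (both strict). Modules smaller than 3 genes have no meaningful
MM-GS correlation and are dropped with a warning.

# Integration, enrichment, and the enrichment map

Per retained module the package computes all seven exclusive regions of
the (dynamic, module, hub) three-set diagram; the signature carried to
enrichment is the dynamic-and-hub intersection, unioned over modules for
tissues with several. Sex-associated modules join the integration only
when listed in `trendedSexModules`: whether a sex module shows a
discernible time trend is a judgment made by inspection, and the package
keeps it an explicit analyst input rather than inventing an automated
rule. Cross-tissue comparisons use the same exclusive-region semantics
("in common between only these tissues").

Over-representation uses the hypergeometric upper tail
`P[X >= k]` on term memberships intersected with the expressed-gene
universe, with in-universe set sizes bounded to [10, 500] (the cited
tool's conventional defaults, exposed as parameters) and BH FDR across
tested terms. GO ancestor propagation is assumed to be baked into the
supplied GMT; no ontology traversal is performed, and identifier mapping
is the caller's responsibility.

The enrichment map connects significant terms whose gene-set similarity
reaches 0.7. The similarity metric defaults to the overlap coefficient
`|A ∩ B| / min(|A|, |B|)` — the published cutoff is named without a
metric, and the overlap coefficient is the least size-biased of the
supported options (Jaccard and their mean are available); sets default to
full in-universe memberships, with a hits-only mode. Clustering is classic
MCL: column-stochastic matrix with self-loops at each node's maximum
incident weight, expansion by squaring, inflation 2.0 with column
renormalization, pruning below 1e-5, convergence at 1e-6 or a warning at
100 iterations; clusters are connected components of the attractor
support, singletons allowed. Cluster labels take up to 4 words scored by
occurrence count plus a bonus of 8 per adjacency to an already-selected
word, greedily; ties break by raw count then alphabetically. The stopword
list is English function words plus "process" and "via"; domain words like
"regulation" are kept because they are informative in GO labels. Meta-nodes
carry the member count and the minimum member FDR (median available);
meta-edges average the cross-cluster edge similarities.

# The synthetic data generator

`simulateAgingData()` draws counts
`NB(mu = depth_s * softmax_g(...), alpha = a1/mu + a0)` with log-scale
structure `b_g + f_g(t) + gamma_g sex + lambda_g e_m + eps`: baseline
abundances `b_g ~ N(3, 1.5)` (natural log), piecewise hinge trajectories
for 120 of 1000 genes (segment slopes 0.15–0.25 per month, 80% with one
breakpoint on the interior grid, sign-reversing at the breakpoint), and
two 80-gene modules driven by latent eigengenes — a tanh shift in age
centred at 15 months, and a sex-tracking profile — with loadings 0.9–1.3
for the 30 hub genes and 0.4–0.9 otherwise, shared per-sample jitter 0.2,
gene-sample noise 0.1, dispersion `a0 = 0.05, a1 = 2`. The design is 9
ages (3–27 months, step 3) × 2 sexes × 2 replicates = 36 samples — the
scale of one tissue in a mouse aging cohort while staying desk-sized.
Library depths are log-normal around 8 million reads; two planted shallow
libraries sit at 2 million (below the depth filter) and one outlier sample
has its gene labels permuted, which preserves its library size and count
distribution while destroying its correlation with every other sample —
precisely the anomaly the sample network detects. The GMT holds 40 terms
(10–60 genes); two planted terms draw 60% of their 40 members from the
age-module hub genes.

Slope magnitudes were chosen so that a single-breakpoint gene's slope
change is large against the VST residual noise (roughly 3 residual SD per
3-month step at typical expression), the regime in which breakpoint
recovery within one grid step is expected of the method; the hub/non-hub
loading split puts hub genes above and non-hub genes below the MM = 0.8
threshold in expectation. Trajectories are specified on the log-mean
scale, so VST-space trends are only approximately the planted piecewise
shapes — recovery tolerances (±one grid step; ≥80–90% rates) account for
this.

What the generator does *not* emulate: empirical mouse count
distributions, gene-length or GC effects, batch structure, correlated
dispersion across genes, unbalanced group sizes, or modules with
heavy-tailed size distributions. Passing the planted-recovery suite
therefore demonstrates that the implementation finds the structure its
models describe at realistic noise levels — not that those models capture
everything in real tissue data.

# Problem sizes and determinism

The test suite and acceptance script run at deliberately modest scales:
1000-gene simulated tissues (36 samples), 2000-gene null matrices for the
permutation calibration, 500-gene networks for recovery checks, 50-gene
matrices for the exact TOM oracle, and 200-gene exactness sweeps against
the brute-force segmented-regression oracle. Every stochastic step
(simulation, permutations) is driven by explicit seeds; the pipeline is a
pure function of (inputs, parameters, seed), which the suite verifies by
comparing two complete runs byte-for-byte.

# Known limitations

- The static tree cut approximates, but is not, the hybrid dynamic tree
  cut; on real data module boundaries will differ from the reference
  implementation, and the liver-style `deepSplit = 4` sensitivity is only
  mimicked by a higher cut.
- The VST dispersion trend is a robust linear fit, adequate for
  variance-flattening but not a replacement for shrinkage-based dispersion
  estimation in differential testing (which this package does not do).
- Breakpoints are restricted to observed ages; shifts between time points
  are assigned to a neighbouring grid point.
- The permutation null shuffles the sample-to-age map globally (sex kept
  attached); a within-sex shuffle would condition on the sex margin and is
  not implemented.
- ORA treats gene sets as flat; no ontology topology, no GSEA-style rank
  statistics.
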
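---
title: "Methods: multi-site cortical morphometry from harmonisation to networks"
author: "megamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site cortical morphometry from harmonisation to networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

Pooling parcellated structural MRI across scanning sites ("mega-analysis")
makes it possible to study clinical contrasts — here the running example is
Parkinson's disease patients with versus without visual hallucinations
(VH / noVH) — at sample sizes no single site can reach. The price is
scanner-induced variance, and the analysis chain this package provides is
built around removing it and then interrogating the harmonised data from
several angles:

1. **Harmonisation** — parametric empirical-Bayes location–scale
   adjustment of site effects (ComBat-type), protecting declared biological
   covariates.
2. **Group mapping** — per-region ANCOVA screening with Benjamini–Hochberg
   control, followed by a covariate-adjusted MANCOVA on the survivors, plus
   the unadjusted VH − noVH difference-of-means map.
3. **Receptor association** — regression of the difference map on PET
   receptor binding-potential maps, with influence diagnostics, bootstrap
   intervals, and spatial-permutation ("spin") inference.
4. **Dimensionality** — correlation-matrix PCA of the group-different
   regions with Kaiser retention, contributions and cos² quality indices.
5. **Structural covariance networks** — inter-regional correlation of
   GLM residuals per group, edge-wise Fisher-z comparison, density-swept
   binary graphs, node metrics, hubs, Louvain communities, and permutation
   and bootstrap inference.

Every stage is exercised end-to-end on synthetic cohorts with known ground
truth; the `eval_*` functions expose those experiments.

# The harmonisation model

For subject $j$ at site $s$, region $r$:

$$y_{jsr} = \alpha_r + X_j \beta_r + \gamma_{sr} + \delta_{sr}\,\varepsilon_{jsr},
\qquad \varepsilon_{jsr} \sim N(0, \sigma_r^2).$$

After estimating $\alpha_r$, $\beta_r$, $\sigma_r$ by least squares (the
grand mean $\alpha_r$ is the site-size-weighted mean of the per-site
intercepts, which fixes the identifiability of the $\gamma$'s), data are
standardized and per-site location/scale effects estimated. Shrinkage pools
them across regions: a normal prior on locations, an inverse-gamma prior on
squared scales, hyperparameters by method of moments, posterior means
iterated until the largest absolute change is below `tol = 1e-6` (at most
200 iterations; non-convergence warns, never errors). The adjusted value is

$$y^{adj}_{jsr} = \frac{\hat\sigma_r}{\delta^*_{sr}}
\left(z_{jsr} - \gamma^*_{sr}\right) + \hat\alpha_r + X_j\hat\beta_r.$$

Choices worth stating:

* **Protected covariates** default to `group + age + gender + tiv`:
  protecting the contrast of interest is the point of covariate-aware
  harmonisation. Configurable per call.
* **No reference-batch mode**: data are standardized to the pooled mean,
  the common usage for multi-site pooling.
* Each morphometric kind (thickness, area, volume) is harmonised
  separately; TIV is metadata and never harmonised.
* `eb = FALSE` is available for the raw (unshrunk) location–scale
  adjustment; with two sites, no covariates and no shrinkage the
  adjustment removes empirical site means exactly, which the tests use as
  a closed-form check. The shrunken fit is verified in the test suite
  against an independent reference implementation to ~1e-7.

# Group mapping

Screening fits, per region, the ANCOVA $y = \text{covariates} +
\text{group}$ and tests the group term; BH step-up runs over all regions of
one measure (148 thickness regions form one family; families are never
pooled across measures). Constant regions yield `p = NaN` and leave the
family with a message. The MANCOVA enters the flagged regions as a
multivariate response; terms are tested sequentially with group last, so
the group test is adjusted for every covariate. The default multivariate
statistic is **Pillai's trace** (robust to covariance heterogeneity;
Wilks available) — the source analyses report multivariate F without naming
the statistic, so this is a documented package decision. Effect sizes are
**partial** eta squared; the reported covariate effect sizes in this
literature exceed what non-partial eta squared could jointly allow, which
fixes the flavour. Pairwise group contrasts are Bonferroni-corrected with
family size equal to the number of regions entered into that MANCOVA.

Outlier flagging uses the Tukey $1.5\,\mathrm{IQR}$ rule with quartiles by
linear interpolation of order statistics (R type 7). The convention only
matters for tiny samples and is fixed for reproducibility. Missing clinical
scores are filled with the sample mean by default (the per-group mode is an
argument), matching how missing motor scores were handled in the pooled
analyses this package re-implements. Partial correlations are residual
Pearson correlations with $df = n - 2 - k$. The demographics table uses
one-way ANOVA for continuous variables, chi-square without continuity
correction (configurable) for categorical ones, and the Brown–Forsythe
(median-centred) Levene test for variance homogeneity. Study-level pooling
uses DerSimonian–Laird random effects with inverse-variance weights and a
Wald interval.

# Receptor associations and the spin test

The difference map (VH − noVH, with pooled-variance SE; planted thinning
therefore shows as negative values for thickness) is regressed on each
receptor's parcel-level binding potential. Reported per fit: the
standardized slope (equal to the Pearson correlation in a simple
regression — asserted numerically in the tests), $t$, $p$, and a seeded
percentile bootstrap interval for the unstandardized slope (default 10,000
resamples). Cook's distance is computed for every point; points with
$D > 1$ are reported and, by default, removed for a refit — both fits are
kept, the post-removal one is the headline. Three region subsets mirror the
standard reporting: significant regions, all regions, non-significant
regions. Slope comparisons between receptors use a stacked interaction
test on standardized predictors.

Spatial autocorrelation makes naive parametric p-values anti-conservative,
so correlations are also tested against a **spin null**: each of
`n_spins` permutations draws a uniform random rotation (QR of a Gaussian
matrix, determinant $+1$), rotates left-hemisphere centroids by it and
right-hemisphere centroids by its x-mirrored counterpart, and reassigns
regions to nearest original centroids by greedy minimal-angular-distance
matching (global greedy; ties resolved by the first minimum in
column-major order). This requires a symmetric atlas — equal region counts
per hemisphere with mirror pairing — and asymmetric atlases are refused.
The p-value is two-sided on $|r|$:
$p = (1 + \#\{|r_{null}| \ge |r_{obs}|\}) / (1 + n_{spins})$, invariant to
affine rescaling of either map. Default 10,000 spins for analyses; the
test-suite experiments use 1,000 for runtime.

**Known limitation.** Bijective parcel-rotation nulls lose calibration as
map smoothness grows: the rotated lattice never aligns exactly with
itself, so reassignment mildly scrambles the spun map and narrows the null.
The packaged calibration experiment (`eval_spin_calibration`) measures
this directly: at white-noise smoothness the empirical type-I error at
$\alpha = 0.05$ is nominal (~0.046), while at the default simulation
smoothness of 20° it inflates to ~0.09–0.11, and power at a planted map
correlation of 0.5 is ~0.83–0.86 rather than near-certain. We verified the
effect is not an artifact of the greedy matching — replacing it with an
exact optimal (Hungarian) assignment reproduces the inflation — so it is
a property of parcel-permutation nulls on strongly autocorrelated fields,
consistent with published benchmarks of these methods. Users comparing very
smooth maps should read spin p-values near the threshold with caution.

# PCA

PCA runs on the region-by-region correlation matrix (regions share units
but not variances, and standardized PCA matches the toolchains this
analysis style uses). Loadings are eigenvectors scaled by
$\sqrt{\lambda}$; contributions are $100 \cdot v^2$ per component; cos² is
the squared loading (summing to 1 per region across all components). The
sign convention — the largest-|loading| entry of each component is made
positive — makes loadings reproducible across implementations. Retention is
the Kaiser rule (eigenvalue > 1) by default. The PCA input is the flagged
thickness regions from screening; harmonised subject-level values are used
directly (a covariate-residualized mode is a one-liner with
`residualize()`, but the default mirrors the source toolchain).

# Structural covariance networks

Residuals from per-region GLMs on age and gender (full sample) are
correlated within each group; a Brown–Forsythe homogeneity check across
groups is reported as a warning only. Edges are compared with the Fisher
z statistic for two independent correlations,
$z = (z_1 - z_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-sided, BH-FDR over
all unordered pairs; the $|r_a^2 - r_b^2| > 0.3$ rule seen in circular
plots is a display filter, applied downstream and never during inference.
Correlations at exactly $|r| = 1$ are clamped to $1 - 10^{-12}$ with a
warning.

Graphs keep the $k$ most positive correlations,
$k = \mathrm{round}(d \cdot R(R-1)/2)$ with round-half-even, ties broken by
lexicographic pair order (deterministic graphs across platforms); negative
correlations never enter, even if $k$ is unmet. The sweep is
$d \in [0.05, 0.20]$ in steps of 0.01 (16 densities, display density 0.13).
Betweenness is unnormalized with fractional attribution over equal-length
shortest paths — the hub rule depends only on within-density ranking, which
is convention-invariant. Nodal efficiency is the mean inverse shortest-path
length to all other nodes (disconnected pairs contribute 0); **local
efficiency** is the global efficiency of the neighbour-induced subgraph —
the classic definition, computed and labelled separately from nodal
efficiency because the two are often conflated. A node is a **hub** when
its betweenness exceeds the mean plus one SD across nodes at a density, at
no fewer than $\lceil 16/2 \rceil = 8$ of the 16 densities. Louvain runs
with a fixed seed and 100 restarts keeping the best modularity; community
labels are canonicalized by descending size. Permutation tests rebuild
everything (covariance → threshold → metric) per label shuffle; the
per-density mode with FDR across nodes × densities is the default, with
density-averaging available (more stable when block structure saturates
low densities). The modularity bootstrap resamples subjects within group
at a fixed density and summarizes the Louvain Q distribution.

# The synthetic cohort generator

`generate_cohort()` draws from

$$y_{jr} = \text{base}_r + \textstyle\sum_c \beta_{cr}(x_{cj} - \bar x_c)
+ \delta_r\,[g_j = \mathrm{VH}] + (\Lambda_{g_j} f_j)_r
+ \text{shift}_{s_jr} + \text{scale}_{s_jr}\,\sigma_r\,\varepsilon_{jr}$$

with standard-normal factor scores and noise. Defaults encode the study
conditions the pipeline is validated under:

| Parameter | Default | Why |
|---|---|---|
| baseline | 2.5 mm | typical regional cortical thickness |
| noise SD $\sigma_r$ | 0.15 mm | typical between-subject regional SD |
| group effect $\delta$ | $-0.3\sigma$ in 10 mirrored pairs | region-sparse thinning at a realistic effect size |
| site shift SD | 0.1 mm | additive scanner offsets |
| site scale SD (log) | 0.15 | multiplicative scanner noise differences |
| age | Normal(66, 8.5) y, truncated [40, 90] | cohort demographics scale |
| TIV | Normal(1.45e6, 1.5e5) mm³ | head-size covariate scale |
| gender | Bernoulli(0.4 F) | cohort sex ratio scale |
| covariate slopes | age −0.008 mm/y, female −0.02 mm, TIV 1.5e-7 mm/mm³ | small realistic thickness effects |
| receptor/null map smoothness | 20° angular scale | moderate parcel-level spatial autocorrelation |

The NPI hallucination subscale (frequency × severity) has no published
distribution; VH subjects draw from a zero-free discrete distribution on
the attainable products {1, 2, 3, 4, 6, 8, 9, 12} with probabilities
decaying toward severe scores, noVH subjects score 0, and 10% of values
are missing at random. This is an assumption, stated as such.

Network ground truth is planted through the loading matrices
(`network_truth()`): each community is a block loading on its own factor
(default block loading 0.15 = 1 noise SD, giving within-community residual
correlation 0.5), and the optional bridge hub loads on *every* community
factor with the same loading — the natural archetype of a
high-betweenness node, giving hub-to-community correlations of ~0.41.
Planting the hub in one group only creates a true between-group network
difference for power experiments. The PCA recovery experiment plants a
four-region block at within-block correlation 0.75 and a two-region block
at 0.34, i.e. population eigenvalues 3.25 and 1.34 among six regions —
mirroring the separation reported for pooled cortical-thickness components
— sampled at the pooled-study scale of 500 subjects.

What the generator deliberately does **not** emulate: image space (no
voxels or surfaces, no segmentation failure modes), non-Gaussian residuals,
site-by-covariate interactions, spatially structured group effects beyond
the planted region set, and missingness outside the NPI score. Passing
recovery tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to everything real
multi-site data can do.

Seeding: every generator and every stochastic analysis takes an explicit
seed and restores the caller's RNG state. A single pipeline seed fans out
into named child seeds drawn in a fixed documented order (atlas, truth,
cohort, receptors, spins, permutations, bootstraps), so stages can be
re-run independently and the whole run is byte-reproducible.

# Problem sizes in the packaged experiments

The validation experiments are sized to be re-runnable on a laptop while
keeping Monte-Carlo error well inside the asserted bounds: harmonisation
recovery uses 10 cohorts of ~200 subjects × 148 regions; screening
recovery 20 cohorts at 400 subjects per group; spin calibration 500 null
dataset pairs × 1,000 spins with a fresh spin set every 25 datasets (so
the estimate is marginal over spin sets rather than conditional on one);
edge calibration 2,000 simulated group pairs at n = 100 each; bootstrap
coverage 500 regressions × 1,000 resamples; hub recovery 50 cohorts;
PCA recovery 50 cohorts of 500 subjects. Analyses of real data should use
the full defaults (10,000 spins, 10,000 bootstrap cycles, 5,000
permutations) — the reduced counts are experiment-design choices for the
validation suite only.

# Known limitations

* The spin-test calibration issue at high smoothness discussed above.
* The MANCOVA's multivariate statistic uses sequential (group-last) tests;
  covariate rows in the multivariate table are order-dependent, the group
  row is not.
* Harmonisation assumes the location–scale model; site-by-biology
  interactions are outside it.
* Louvain is a heuristic; the packaged oracle tests bound it by exhaustive
  search only on small graphs.
* The permutation test rebuilds group networks per shuffle, which is the
  statistically honest scheme but makes 5,000-cycle runs on 68-region
  data a coffee-break computation rather than an interactive one.
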
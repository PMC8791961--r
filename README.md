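# megamorph

Pooled ("mega-analytic") studies of cortical morphometry combine
parcellated thickness, surface-area and volume tables from many scanning
sites to study a clinical contrast — the motivating case is Parkinson's
disease patients with versus without visual hallucinations (VH / noVH) —
at sample sizes no single site can reach. Pooling buys power and pays in
scanner-induced variance. `megamorph` implements the full analysis chain
for this setting, for R users who have subjects × regions tables and
metadata rather than images:

* **Harmonisation.** Parametric empirical-Bayes location–scale adjustment
  (ComBat-type). For subject *j*, site *s*, region *r*:
  *y* = α<sub>r</sub> + Xβ<sub>r</sub> + γ<sub>sr</sub> +
  δ<sub>sr</sub>ε, with normal/inverse-gamma priors shrinking the
  per-site location and scale effects across regions, while declared
  biological covariates (group, age, gender, TIV by default) are
  protected. `fit_combat()` / `apply_combat()` separate estimation from
  application; `site_effect_report()` audits site η² before and after.
* **Group mapping.** `screen_regions_anova()` (per-region ANCOVA with
  Benjamini–Hochberg control over the regions of one measure),
  `fit_mancova()` (Pillai's trace by default, per-region partial η²,
  Bonferroni pairwise contrasts), `compute_difference_map()`
  (VH − noVH difference of means with pooled SE), plus Tukey 1.5·IQR
  outlier flags, mean imputation, partial correlations,
  DerSimonian–Laird meta-analysis, leave-one-study-out reruns and
  demographics tables.
* **Receptor associations.** `fit_receptor_regression()` regresses the
  difference map on PET binding-potential maps (standardized slope,
  Cook's-distance influence workflow, seeded percentile bootstrap CI);
  `generate_spin_permutations()` + `spin_correlation_test()` give
  spatial-permutation p-values that respect spatial autocorrelation:
  p = (1 + #{|r_null| ≥ |r_obs|}) / (1 + n_spins).
* **PCA.** `run_pca()` on the region correlation matrix with
  contributions and cos²; `select_components()` applies the Kaiser rule
  (eigenvalue > 1).
* **Covariance networks.** `residualize()` → `covariance_matrix()` →
  `compare_edges()` (Fisher z, BH-FDR over all pairs) →
  `threshold_graph()` (top-k positive correlations across a density sweep
  0.05–0.20) → `node_metrics()` (degree, betweenness, nodal/local/global
  efficiency) → `identify_hubs()` (betweenness > mean + 1 SD at ≥ half
  the densities) → `detect_communities()` (seeded Louvain with restarts),
  with `permutation_test_metrics()` and `bootstrap_modularity()` for
  inference.
* **Synthetic cohorts with known truth.** `generate_atlas()`,
  `cohort_truth()`, `network_truth()`, `generate_cohort()`,
  `generate_receptor_map()`, `generate_smooth_null_maps()` emulate site
  effects, covariate effects, region-sparse group thinning, planted
  communities/hubs and smooth receptor fields — the substrate for every
  calibration and recovery experiment (`eval_*` functions).

`run_pipeline()` chains all stages from one seeded configuration and
returns a machine-readable report.

## Worked example

A synthetic three-site cohort (480 subjects, 68 regions) with planted
cortical thinning in 20 regions, a planted two-community covariance
structure with a bridge hub, one receptor map blended to correlation 0.5
with the true difference map and one unrelated receptor map:

```r
library(megamorph)
cfg <- list(
  synthetic = list(n_per_hemisphere = 34L, n_sites = 3L,
                   n_per_group_per_site = 80L, plant_network = TRUE,
                   receptors = list(list(label = "fallypride_d2", rho = 0.5),
                                    list(label = "cimbi36_5ht2a", rho = 0))),
  n_spins = 1000L, n_boot = 1000L, seed = 7L)
rep <- run_pipeline(cfg)
print(rep)
#> Pipeline report
#>   site eta2: 0.1433 -> 0.0002
#>   flagged regions: 20
#>   receptor fallypride_d2: spin r = 0.493, p = 0.0040
#>   receptor cimbi36_5ht2a: spin r = 0.001, p = 0.9940
#>   PCA: 3 dimensions retained
#>   network: 0/2278 edges FDR-significant; Q(VH) = 0.426, Q(noVH) = 0.442
```

Reading this: harmonisation cut the mean site-factor η² from 0.14 to
0.0002 while all 20 planted thinning regions survived screening; the
receptor map constructed to correlate with the difference map shows
r = 0.49 with spin p = 0.004, the unrelated one r ≈ 0 with p = 0.99; and
the planted bridge hub (region `L_021`) appears in the hub set of the
group whose network carries it:

```r
rep$network$hubs_no
#> [1] "L_021" "L_027" "R_020" "R_025" "R_029"
rep$receptor$fallypride_d2$fits$all$beta_std
#> [1] 0.4932  # standardized slope = Pearson r for a simple regression
```

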
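Package: megamorph
Title: Multi-Site Cortical Morphometry: Harmonisation, Group Mapping,
    Receptor Associations and Structural Covariance Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled (mega-analytic) studies of parcellated cortical
    morphometry across scanning sites. Provides parametric empirical-Bayes
    location-scale harmonisation of multi-site morphometric tables, region
    screening with Benjamini-Hochberg control and covariate-adjusted
    multivariate group comparison, group difference maps, spatial-permutation
    ("spin") inference for associations between difference maps and PET
    receptor binding-potential maps, correlation-matrix principal component
    analysis, and structural covariance network construction and comparison
    (density thresholding, node metrics, hubs, Louvain communities,
    permutation and bootstrap inference). A synthetic-cohort generator with
    known ground truth (site effects, covariate effects, planted group
    differences, latent-factor covariance, smooth receptor fields) supports
    calibration and recovery experiments for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    igraph,
    jsonlite,
    metafor,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
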
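test_that("BH adjustment matches the hand step-up rule", {
  # the worked example: four evenly spaced p-values all adjust to the max
  atl <- tiny_atlas
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # property: p.adjust-based path equals the independent step-up oracle
  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("screening controls FDR under the null and finds planted effects", {
  atl <- tiny_atlas
  tr0 <- cohort_truth(atl, n_sites = 1, delta = 0, site_shift_sd = 0,
                      site_scale_sdlog = 0, seed = 5)
  nrej <- vapply(1:25, function(s) {
    coh <- generate_cohort(atl, tr0, matrix(30L, 1, 2), seed = 600 + s)
    sum(screen_regions_anova(coh$values, coh$meta)$flagged)
  }, numeric(1))
  expect_lte(mean(nrej / 16), 0.05)

  tr1 <- cohort_truth(atl, n_sites = 1, site_shift_sd = 0,
                      site_scale_sdlog = 0, seed = 5)
  coh <- generate_cohort(atl, tr1, matrix(300L, 1, 2), seed = 9)
  scr <- screen_regions_anova(coh$values, coh$meta)
  planted <- names(tr1$delta)[tr1$delta != 0]
  expect_gte(mean(planted %in% scr$region_id[scr$flagged]), 0.8)
  # thinning planted in VH: negative direction for thickness
  expect_true(all(scr$direction[match(planted, scr$region_id)] == -1))
  # monotone step-up consistency
  expect_true(all(scr$p_fdr >= scr$p))
})

test_that("screening excludes constant regions from the FDR family", {
  coh <- make_cohort(tiny_atlas, n_sites = 1, n = 20,
                     site_shift_sd = 0, site_scale_sdlog = 0)
  vals <- coh$values
  vals[, 3] <- 1.0
  expect_message(scr <- screen_regions_anova(vals, coh$meta), "constant")
  expect_true(is.na(scr$p_fdr[3]))
  expect_false(scr$flagged[3])
})

test_that("MANCOVA reduces to ANOVA for one region and matches hand sums", {
  # groups {1,2} vs {3,4}: SSb = 4, SSw = 1, F(1,2) = 8, eta2 = 0.8
  values <- matrix(c(1, 2, 3, 4), 4, 1,
                   dimnames = list(paste0("s", 1:4), "r1"))
  meta <- data.frame(subject_id = paste0("s", 1:4), site = "a",
                     group = c("noVH", "noVH", "VH", "VH"))
  res <- fit_mancova(values, meta, "r1", covariates = character())
  expect_equal(res$per_region$F, 8)
  expect_equal(res$per_region$df1, 1)
  expect_equal(res$per_region$df2, 2)
  expect_equal(res$per_region$partial_eta2, 0.8)
  # one dependent variable: multivariate p equals the univariate p
  expect_equal(res$multivariate$p[res$multivariate$term == "group"],
               res$per_region$p)
  # Bonferroni with m = 1 leaves p unchanged
  expect_equal(res$pairwise$p_bonferroni, res$pairwise$p)
})

test_that("Pillai p-values are calibrated for null multivariate data", {
  atl <- tiny_atlas
  tr0 <- cohort_truth(atl, n_sites = 1, delta = 0, site_shift_sd = 0,
                      site_scale_sdlog = 0, seed = 5)
  ps <- vapply(1:40, function(s) {
    coh <- generate_cohort(atl, tr0, matrix(100L, 1, 2), seed = 700 + s)
    res <- fit_mancova(coh$values, coh$meta, atl$region_id[1:2],
                       covariates = character())
    res$multivariate$p[res$multivariate$term == "group"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("MANCOVA Bonferroni counts the regions entered", {
  coh <- make_cohort(tiny_atlas, n_sites = 1, n = 40, site_shift_sd = 0,
                     site_scale_sdlog = 0)
  res <- fit_mancova(coh$values, coh$meta, colnames(coh$values)[1:5])
  expect_equal(res$pairwise$p_bonferroni, pmin(1, 5 * res$pairwise$p))
  expect_error(fit_mancova(coh$values, coh$meta, character()), "nonempty")
})

test_that("difference maps follow their construction", {
  coh <- make_cohort(tiny_atlas, n_sites = 1, n = 20, delta = 0,
                     site_shift_sd = 0, site_scale_sdlog = 0)
  vals <- coh$values
  vh <- coh$meta$group == "VH"
  # identical groups: diff exactly zero
  vals[vh, ] <- vals[!vh, ]
  dm0 <- compute_difference_map(vals, coh$meta)
  expect_true(all(dm0$diff == 0))
  # constant offset: diff exactly the offset
  vals[vh, ] <- vals[!vh, ] + 0.3
  dm3 <- compute_difference_map(vals, coh$meta)
  expect_true(all(abs(dm3$diff - 0.3) < 1e-12))
})

test_that("pooled-variance SE agrees with a bootstrap", {
  set.seed(11)
  n <- 100
  x <- rnorm(2 * n, sd = 1.3)
  values <- matrix(x, 2 * n, 1, dimnames = list(paste0("s", 1:(2 * n)), "r"))
  meta <- data.frame(subject_id = rownames(values), site = "a",
                     group = rep(c("VH", "noVH"), each = n))
  dm <- compute_difference_map(values, meta)
  boot <- replicate(2000, {
    mean(sample(x[1:n], n, TRUE)) - mean(sample(x[n + 1:n], n, TRUE))
  })
  expect_equal(dm$se, sd(boot), tolerance = 0.1)
})

test_that("Tukey fences use interpolated quartiles", {
  expect_equal(flag_outliers_tukey(c(2, 4, 4, 5, 6, 7, 100)), 7L)
  expect_length(flag_outliers_tukey(1:10), 0)
  x <- c(-100, rnorm(20), 100)
  expect_setequal(flag_outliers_tukey(x), c(1L, 22L))
  expect_error(flag_outliers_tukey(c(1, 2, 3)), "4 finite")
})

test_that("mean imputation fills only the missing entries", {
  expect_equal(impute_group_mean(c(1, 2, NA)), c(1, 2, 1.5))
  x <- c(4, 2, 7)
  expect_identical(impute_group_mean(x), x)
  # pooled default vs per-group mode
  v <- c(1, NA, 3, 5)
  g <- c("A", "A", "B", "B")
  expect_equal(impute_group_mean(v), c(1, 3, 3, 5))
  expect_equal(impute_group_mean(v, g), c(1, 1, 3, 5))
  expect_error(impute_group_mean(c(NA, NA, 1), c("A", "A", "B")), "group")
})

test_that("partial correlation matches its recursion formula exactly", {
  B <- orthonormal_basis(200, 3)
  x <- B[, 1]
  z <- 0.5 * B[, 1] + sqrt(0.75) * B[, 2]
  a <- 0.25 / sqrt(0.75)
  y <- 0.5 * B[, 1] + a * B[, 2] + sqrt(1 - 0.25 - a^2) * B[, 3]
  # sample correlations are exact by construction
  expect_equal(cor(x, z), 0.5, tolerance = 1e-12)
  expect_equal(cor(y, z), 0.5, tolerance = 1e-12)
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, (0.5 - 0.25) / 0.75, tolerance = 1e-10)
  expect_equal(pc$df, 200 - 3)
  # constant covariate: partial r equals plain r
  pc0 <- partial_correlation(x, y, rep(1, 200))
  expect_equal(pc0$r, 0.5, tolerance = 1e-10)
  # y = x: r = 1 and p underflows to 0
  pc1 <- partial_correlation(x, x, z)
  expect_equal(pc1$r, 1)
  expect_lt(pc1$p, 1e-100)
})

test_that("random-effects pooling matches hand computations", {
  m <- meta_analyze(c(2, 2), c(1, 1))
  expect_equal(m$estimate, 2)
  expect_equal(m$tau2, 0)
  expect_equal(m$se, sqrt(0.5), tolerance = 1e-10)
  expect_equal(meta_analyze(c(1, -1), c(0.5, 0.5))$estimate, 0)
  expect_gt(meta_analyze(c(0, 4), c(0.1, 0.1))$tau2, 0)
  expect_warning(m1 <- meta_analyze(3, 2), "single study")
  expect_equal(m1$estimate, 3)
  expect_error(meta_analyze(c(1, 2), c(1, 0)), "positive")
})

test_that("leave-one-study-out reruns are consistent on homogeneous sites", {
  atl <- tiny_atlas
  tr <- cohort_truth(atl, n_sites = 4, site_shift_sd = 0,
                     site_scale_sdlog = 0, seed = 13)
  coh <- generate_cohort(atl, tr, 100, seed = 17)
  loo <- leave_one_study_out(coh$values, coh$meta)
  expect_length(loo$runs, 4)
  jac <- vapply(loo$runs, `[[`, numeric(1), "jaccard")
  expect_true(all(jac >= 0.8))
  # deterministic
  loo2 <- leave_one_study_out(coh$values, coh$meta)
  expect_identical(lapply(loo$runs, `[[`, "flagged"),
                   lapply(loo2$runs, `[[`, "flagged"))
})

test_that("demographic comparisons use uncorrected chi-square by default", {
  meta <- data.frame(
    subject_id = sprintf("s%03d", 1:100), site = "a",
    group = rep(c("VH", "noVH"), each = 50),
    gender = c(rep("F", 25), rep("M", 25), rep("F", 10), rep("M", 40)),
    age = rnorm(100, 65, 8)
  )
  out <- compare_demographics(meta)
  chi <- out[out$variable == "gender", ]
  expect_equal(chi$statistic, 9.890, tolerance = 1e-3)
  # identical proportions: chi-square 0, p = 1
  meta2 <- meta
  meta2$gender <- rep(c(rep("F", 30), rep("M", 20)), 2)
  chi2 <- compare_demographics(meta2)
  chi2 <- chi2[chi2$variable == "gender", ]
  expect_equal(chi2$statistic, 0)
  expect_equal(chi2$p, 1)
})

test_that("Levene p-values are roughly uniform for equal variances", {
  set.seed(21)
  ps <- replicate(200, {
    meta <- data.frame(subject_id = sprintf("s%03d", 1:60), site = "a",
                       group = rep(c("VH", "noVH"), each = 30),
                       age = rnorm(60))
    compare_demographics(meta, continuous = "age",
                         categorical = character())$levene_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  expect_gt(mean(ps < 0.05), 0.0)  # sanity: they vary
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("partial eta squared is invariant under affine rescaling", {
  coh <- make_cohort(tiny_atlas, n_sites = 1, n = 30, site_shift_sd = 0,
                     site_scale_sdlog = 0)
  scr1 <- screen_regions_anova(coh$values, coh$meta)
  scr2 <- screen_regions_anova(coh$values * 3.7 + 11, coh$meta)
  expect_equal(scr1$partial_eta2, scr2$partial_eta2, tolerance = 1e-10)
  expect_equal(scr1$F, scr2$F, tolerance = 1e-10)
})
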
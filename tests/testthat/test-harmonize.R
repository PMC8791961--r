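test_that("null site effects yield near-identity adjustments", {
  atl <- tiny_atlas
  tr <- cohort_truth(atl, n_sites = 2, site_shift_sd = 0,
                     site_scale_sdlog = 0, seed = 3)
  coh <- generate_cohort(atl, tr, 100, seed = 5)
  fit <- fit_combat(coh$values, coh$meta)
  expect_true(all(abs(fit$gamma_star) < 0.05))
  expect_true(all(abs(fit$delta_star - 1) < 0.05))
})

test_that("a planted additive shift is estimated in standardized units", {
  atl <- tiny_atlas
  tr <- cohort_truth(atl, n_sites = 2, delta = 0, site_shift_sd = 0,
                     site_scale_sdlog = 0, seed = 3)
  coh <- generate_cohort(atl, tr, 100, seed = 7)
  shifted <- coh$values
  b <- coh$meta$site == "site2"
  shifted[b, ] <- shifted[b, ] + 1.0
  fit <- fit_combat(shifted, coh$meta, biological_covariates = character())
  # raw (unshrunk) site-location gap in standardized units is the planted
  # shift over sigma; site2 sits at +half of it (alpha is the 50/50 mean)
  gap_units <- (fit$gamma_hat["site2", ] - fit$gamma_hat["site1", ]) *
    fit$sigma
  expect_equal(mean(gap_units), 1.0, tolerance = 0.02)
  expect_true(all(abs(gap_units - 1.0) < 0.15))
  expect_gt(min(fit$gamma_hat["site2", ] * fit$sigma), 0.3)
})

test_that("identity fit leaves the data untouched and pure shifts vanish", {
  atl <- tiny_atlas
  tr <- cohort_truth(atl, n_sites = 2, site_shift_sd = 0,
                     site_scale_sdlog = 0, seed = 3)
  coh <- generate_cohort(atl, tr, 30, seed = 9)
  fit <- fit_combat(coh$values, coh$meta)
  fit$gamma_star[] <- 0
  fit$delta_star[] <- 1
  adj <- apply_combat(fit, coh$values, coh$meta)
  expect_equal(adj, coh$values, tolerance = 1e-10)

  # two-site pure shift, covariate-free, EB off: closed form removes it
  shifted <- coh$values
  b <- coh$meta$site == "site2"
  shifted[b, ] <- shifted[b, ] + 0.7
  fit2 <- fit_combat(shifted, coh$meta, biological_covariates = character(),
                     eb = FALSE)
  adj2 <- apply_combat(fit2, shifted, coh$meta)
  site_means_gap <- colMeans(adj2[b, ]) - colMeans(adj2[!b, ])
  expect_true(all(abs(site_means_gap) < 1e-6))
})

test_that("harmonisation is idempotent up to EB shrinkage noise", {
  coh <- make_cohort(tiny_atlas, n = 60)
  # without shrinkage (and covariate-free) the adjustment removes the
  # empirical site effects exactly: second-pass locations are zero to
  # machine precision, scales to the n/(n-1) variance-convention gap
  fit_raw <- fit_combat(coh$values, coh$meta,
                        biological_covariates = character(), eb = FALSE)
  adj_raw <- apply_combat(fit_raw, coh$values, coh$meta)
  fit2_raw <- fit_combat(adj_raw, coh$meta,
                         biological_covariates = character(), eb = FALSE)
  expect_true(all(abs(fit2_raw$gamma_hat) < 1e-8))
  expect_true(all(abs(sqrt(fit2_raw$delta2_hat) - 1) < 0.02))
  # with shrinkage, second-pass effects are small but not exactly zero
  # (the shrinkage gap remains, on top of sampling noise)
  fit <- fit_combat(coh$values, coh$meta)
  adj <- apply_combat(fit, coh$values, coh$meta)
  fit2 <- fit_combat(adj, coh$meta)
  expect_true(all(abs(fit2$gamma_hat) < 0.1))
  expect_true(all(abs(sqrt(fit2$delta2_hat) - 1) < 0.15))
})

test_that("group effects survive site confounding when protected", {
  # group 70/30 confounded with site; planted effect must be retained
  atl <- tiny_atlas
  delta_true <- -0.06
  regions <- atl$region_id[1:8]
  bias <- vapply(1:5, function(s) {
    tr <- cohort_truth(atl, n_sites = 2, delta = delta_true,
                       delta_regions = regions, site_shift_sd = 0.15,
                       site_scale_sdlog = 0.1, seed = s)
    n_tab <- matrix(c(280L, 120L, 120L, 280L), 2, 2)  # VH, noVH per site
    coh <- generate_cohort(atl, tr, n_tab, seed = 100 + s)
    fit <- fit_combat(coh$values, coh$meta)
    adj <- apply_combat(fit, coh$values, coh$meta)
    dm <- compute_difference_map(adj, coh$meta)
    est <- mean(dm$diff[match(regions, dm$region_id)])
    est / delta_true - 1
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.10)
})

test_that("our empirical-Bayes fit reproduces the reference implementation", {
  atl <- generate_atlas(10, seed = 1)
  coh <- make_cohort(atl, n = 20)
  fit <- fit_combat(coh$values, coh$meta)
  adj <- apply_combat(fit, coh$values, coh$meta)
  mod <- stats::model.matrix(~ group + age + gender + tiv,
                             data = coh$meta)[, -1]
  ref <- t(sva::ComBat(dat = t(coh$values), batch = coh$meta$site,
                       mod = mod))
  expect_lt(max(abs(adj - ref)), 1e-6)
})

test_that("harmonisation removes site variance and keeps biology", {
  red <- bio <- numeric(3)
  for (s in 1:3) {
    coh <- make_cohort(small_atlas, n = 33, seed = 200 + s)
    pre <- site_effect_report(coh$values, coh$meta)
    fit <- fit_combat(coh$values, coh$meta)
    adj <- apply_combat(fit, coh$values, coh$meta)
    post <- site_effect_report(adj, coh$meta)
    red[s] <- 1 - mean(post$eta2) / mean(pre$eta2)
    bio[s] <- cor(compute_difference_map(coh$values, coh$meta)$diff,
                  compute_difference_map(adj, coh$meta)$diff)
  }
  expect_true(all(red >= 0.9))
  expect_true(all(bio > 0.95))
})

test_that("harmonisation commutes with subject permutation", {
  coh <- make_cohort(tiny_atlas, n = 15)
  fit <- fit_combat(coh$values, coh$meta)
  adj <- apply_combat(fit, coh$values, coh$meta)
  perm <- sample(nrow(coh$values))
  values_p <- coh$values[perm, ]
  fit_p <- fit_combat(values_p, coh$meta)
  adj_p <- apply_combat(fit_p, values_p, coh$meta)
  expect_equal(adj_p, adj[perm, ], tolerance = 1e-10)
})

test_that("degenerate designs are refused with useful messages", {
  coh <- make_cohort(tiny_atlas, n_sites = 1, n = 10)
  expect_error(fit_combat(coh$values, coh$meta), "2 sites")
  coh2 <- make_cohort(tiny_atlas, n = 10)
  meta2 <- coh2$meta
  meta2$age2 <- meta2$age  # exact collinearity
  expect_error(
    fit_combat(coh2$values, meta2,
               biological_covariates = c("age", "age2")),
    "collinear")
  fit <- fit_combat(coh2$values, coh2$meta)
  meta3 <- coh2$meta
  meta3$site[1] <- "siteX"
  expect_error(apply_combat(fit, coh2$values, meta3), "siteX")
})

test_that("site-effect report is calibrated under the null and powered", {
  atl <- small_atlas
  tr0 <- cohort_truth(atl, n_sites = 2, delta = 0, site_shift_sd = 0,
                      site_scale_sdlog = 0, seed = 5)
  # under identical site distributions, p is approximately uniform
  ps <- unlist(lapply(1:3, function(s) {
    coh <- generate_cohort(atl, tr0, 50, seed = 400 + s)
    site_effect_report(coh$values, coh$meta)$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # planted 1 SD shift: overwhelming evidence
  coh <- generate_cohort(atl, tr0, 100, seed = 11)
  shifted <- coh$values
  b <- coh$meta$site == "site2"
  shifted[b, 1:5] <- shifted[b, 1:5] + 0.15  # 1 residual SD
  rep1 <- site_effect_report(shifted, coh$meta)
  expect_true(all(rep1$p[1:5] < 1e-6))
  # single-region table gives one row
  one <- site_effect_report(coh$values[, 1, drop = FALSE], coh$meta)
  expect_equal(nrow(one), 1L)
})
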
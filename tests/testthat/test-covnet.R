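test_that("residualization is exact OLS with zero-mean residuals", {
  coh <- make_cohort(tiny_atlas, n_sites = 1, n = 25, site_shift_sd = 0,
                     site_scale_sdlog = 0)
  res <- suppressWarnings(residualize(coh$values, coh$meta))
  expect_true(all(abs(colMeans(res)) < 1e-10))
  for (j in c(1, 7)) {
    expect_lt(abs(cor(res[, j], coh$meta$age)), 1e-10)
  }
  # values built from age exactly: residuals orthogonal to age
  vals <- coh$values
  vals[, 1] <- 2 * coh$meta$age + rnorm(nrow(vals), sd = 0.01)
  res2 <- suppressWarnings(residualize(vals, coh$meta))
  expect_lt(abs(cor(res2[, 1], coh$meta$age)), 1e-10)
  # covariates orthogonal to values leave correlations unchanged
  n <- nrow(coh$values)
  meta3 <- coh$meta
  B <- qr.Q(qr(cbind(1, scale(coh$values))))
  ortho <- rnorm(n)
  ortho <- ortho - B %*% crossprod(B, ortho)
  meta3$ortho_cov <- as.numeric(ortho)
  res3 <- suppressWarnings(residualize(coh$values, meta3, "ortho_cov"))
  expect_equal(cor(res3), cor(coh$values), tolerance = 1e-10)
})

test_that("covariance matrices match the planted factor model", {
  atl <- tiny_atlas
  net <- network_truth(atl, n_blocks = 2, block_size = 5)
  tr <- cohort_truth(atl, n_sites = 1, delta = 0, site_shift_sd = 0,
                     site_scale_sdlog = 0, loadings = net$loadings, seed = 2)
  coh <- generate_cohort(atl, tr, matrix(400L, 1, 2), seed = 3)
  res <- suppressWarnings(residualize(coh$values, coh$meta))
  cm <- covariance_matrix(res, coh$meta, "VH")
  expect_equal(diag(cm$r), rep(1, 16), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  L <- net$loadings$VH
  implied <- stats::cov2cor(L %*% t(L) + diag(tr$noise_sd^2))
  expect_lt(norm(cm$r - implied, "F"), 0.1 * 16)
  # perfectly coupled regions give r = 1
  res2 <- res
  res2[, 2] <- res2[, 1]
  cm2 <- covariance_matrix(res2, coh$meta, "VH")
  expect_equal(cm2$r[1, 2], 1)
  # constant region refused
  res3 <- res
  res3[coh$meta$group == "VH", 3] <- 0
  expect_error(covariance_matrix(res3, coh$meta, "VH"), "constant")
})

test_that("edge comparison reproduces the Fisher z arithmetic", {
  mk <- function(r12, n) {
    r <- diag(2)
    r[1, 2] <- r[2, 1] <- r12
    dimnames(r) <- list(c("a", "b"), c("a", "b"))
    structure(list(r = r, group_label = "g", n_subjects = n),
              class = "cov_matrix")
  }
  ed <- compare_edges(mk(0.8, 103), mk(0.2, 103))
  expect_equal(ed$z, (atanh(0.8) - atanh(0.2)) / sqrt(2 / 100),
               tolerance = 1e-12)
  expect_equal(ed$z, 6.334, tolerance = 1e-3)
  expect_lt(ed$p, 1e-9)
  expect_equal(ed$delta_r2, 0.8^2 - 0.2^2)
  # equal correlations: z = 0, p = 1
  ed0 <- compare_edges(mk(0.5, 100), mk(0.5, 100))
  expect_equal(ed0$z, 0)
  expect_equal(ed0$p, 1)
  # antisymmetry under group swap
  ed_ab <- compare_edges(mk(0.7, 50), mk(0.3, 80))
  ed_ba <- compare_edges(mk(0.3, 80), mk(0.7, 50))
  expect_equal(ed_ab$z, -ed_ba$z)
  expect_equal(ed_ab$p, ed_ba$p)
  # |r| = 1 clamped with a warning
  expect_warning(compare_edges(mk(1, 30), mk(0.2, 30)), "clamped")
})

test_that("density thresholding keeps the k most positive correlations", {
  set.seed(4)
  R <- 68
  r <- cor(matrix(rnorm(100 * R), 100, R))
  dimnames(r) <- list(paste0("n", 1:R), paste0("n", 1:R))
  tg <- threshold_graph(r, 0.13)
  expect_equal(tg$k, round(0.13 * 68 * 67 / 2))
  expect_equal(tg$k, 296L)
  expect_equal(sum(tg$adjacency) / 2, tg$k)
  expect_true(all(diag(tg$adjacency) == 0))
  # monotone nesting across the sweep
  t05 <- threshold_graph(r, 0.05)
  t20 <- threshold_graph(r, 0.20)
  expect_true(all(t20$adjacency[t05$adjacency == 1] == 1))
  # k = 1 picks the global maximum
  suppressWarnings(t1 <- threshold_graph(r, 1 / (R * (R - 1) / 2)))
  ut <- upper.tri(r)
  expect_equal(sum(t1$adjacency) / 2, 1)
  expect_equal(r[which(t1$adjacency == 1)][1], max(r[ut]))
  # negative correlations never enter
  rneg <- -abs(r)
  diag(rneg) <- 1
  expect_warning(tn <- threshold_graph(rneg, 0.13), "positive")
  expect_equal(sum(tn$adjacency), 0)
  expect_error(threshold_graph(r, 0), "density")
})

test_that("node metrics agree exactly with brute-force oracles", {
  # hand example: path a-b-c
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
                  dimnames = list(letters[1:3], letters[1:3]))
  nm <- node_metrics(path3)
  expect_equal(nm$nodes$betweenness, c(0, 1, 0))
  expect_equal(nm$nodes$nodal_efficiency[2], 1)
  expect_equal(nm$global_efficiency, (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  # complete graph K4: all efficiencies 1
  k4 <- matrix(1, 4, 4) - diag(4)
  nm4 <- node_metrics(k4)
  expect_true(all(nm4$nodes$nodal_efficiency == 1))
  expect_true(all(nm4$nodes$local_efficiency == 1))
  expect_equal(nm4$global_efficiency, 1)
  # 200 random graphs with <= 7 nodes: exact equality with enumeration
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:7, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.8))
    nm_i <- node_metrics(adj)
    orc <- oracle_efficiencies(adj)
    expect_equal(nm_i$nodes$degree, as.integer(rowSums(adj)))
    expect_equal(nm_i$nodes$betweenness, oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(nm_i$nodes$nodal_efficiency, orc$nodal, tolerance = 1e-12)
    expect_equal(nm_i$nodes$local_efficiency, orc$local, tolerance = 1e-12)
    expect_equal(nm_i$global_efficiency, orc$global, tolerance = 1e-12)
  }
})

test_that("Louvain attains the known optima on the triangle fixtures", {
  two_tri <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    two_tri[e[1], e[2]] <- two_tri[e[2], e[1]] <- 1L
  }
  cm <- detect_communities(two_tri, seed = 3, restarts = 20)
  expect_equal(cm$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(cm$membership)), 2L)
  expect_equal(unname(cm$membership[1]), unname(cm$membership[2]))
  expect_false(cm$membership[[1]] == cm$membership[[4]])
  # bridged triangles: Q = 2 * (3/7 - (7/14)^2) = 5/14
  bridged <- two_tri
  bridged[3, 4] <- bridged[4, 3] <- 1L
  cb <- detect_communities(bridged, seed = 3, restarts = 20)
  expect_equal(cb$Q, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-12)
  expect_equal(cb$Q, oracle_best_modularity(bridged), tolerance = 1e-12)
  # complete graph: single community, Q = 0 is the best achievable
  k5 <- matrix(1, 5, 5) - diag(5)
  ck <- detect_communities(k5, seed = 1, restarts = 10)
  expect_gte(ck$Q, 0)
  expect_error(detect_communities(matrix(0, 3, 3)), "no edges")
})

test_that("Louvain never exceeds the exhaustive optimum on small graphs", {
  set.seed(21)
  sizes <- c(rep(5:8, times = c(12, 12, 12, 10)), 9, 9)
  for (n in sizes) {
    adj <- random_adj(n, runif(1, 0.25, 0.7))
    if (sum(adj) == 0) next
    got <- detect_communities(adj, seed = 5, restarts = 30)$Q
    best <- oracle_best_modularity(adj)
    expect_lte(got, best + 1e-10)
  }
})

test_that("the hub rule counts qualifications across the density sweep", {
  # synthetic betweenness: node 1 exceeds mean+sd at exactly 8 of 16
  # densities, node 2 at 7
  set.seed(6)
  base <- matrix(rnorm(20 * 16, 10, 1), 20, 16,
                 dimnames = list(paste0("n", 1:20), NULL))
  qual_target <- function(b, col, hot) {
    thr <- mean(b[, col]) + sd(b[, col])
    if (hot) b[1, col] <- thr + 5 else b[1, col] <- thr - 5
    b
  }
  b <- base
  for (cc in 1:16) b <- qual_target(b, cc, cc <= 8)
  hubs <- identify_hubs(b)
  expect_equal(hubs$threshold, 8L)
  expect_true("n1" %in% hubs$hubs)
  b2 <- base
  for (cc in 1:16) b2 <- qual_target(b2, cc, cc <= 7)
  expect_false("n1" %in% identify_hubs(b2)$hubs)
  # star graph: the centre always qualifies
  star <- matrix(0L, 8, 8, dimnames = list(paste0("s", 1:8), paste0("s", 1:8)))
  star[1, 2:8] <- star[2:8, 1] <- 1L
  bstar <- cbind(node_metrics(star)$nodes$betweenness,
                 node_metrics(star)$nodes$betweenness)
  rownames(bstar) <- rownames(star)
  expect_equal(identify_hubs(bstar)$hubs, "s1")
  # zero-variance betweenness: nobody qualifies at that density
  flat <- matrix(1, 5, 2, dimnames = list(paste0("f", 1:5), NULL))
  expect_length(identify_hubs(flat)$hubs, 0)
})

test_that("planted bridge hubs are recovered from synthetic cohorts", {
  out <- eval_hub_recovery(n_seeds = 15, seed = 31)
  expect_gte(out$recovery_rate, 0.9)
})

test_that("metric permutation tests are calibrated and detect planted hubs", {
  atl <- generate_atlas(15, seed = 1)   # 30 regions for speed
  net0 <- network_truth(atl, n_blocks = 2, block_size = 8, hub = TRUE,
                        hub_group = "both")
  tr0 <- cohort_truth(atl, n_sites = 1, delta = 0, site_shift_sd = 0,
                      site_scale_sdlog = 0, loadings = net0$loadings,
                      seed = 2)
  # null: both groups share the network; few FDR hits expected
  nsig <- vapply(1:6, function(s) {
    coh <- generate_cohort(atl, tr0, matrix(60L, 1, 2), seed = 800 + s)
    res <- suppressWarnings(residualize(coh$values, coh$meta))
    pt <- permutation_test_metrics(res, coh$meta, densities = 0.13,
                                   n_perm = 200, seed = s)
    sum(pt$p_fdr <= 0.05)
  }, numeric(1))
  expect_lte(mean(nsig), 1)
  expect_error(permutation_test_metrics(
    suppressWarnings(residualize(
      generate_cohort(atl, tr0, matrix(20L, 1, 2), seed = 1)$values,
      generate_cohort(atl, tr0, matrix(20L, 1, 2), seed = 1)$meta)),
    generate_cohort(atl, tr0, matrix(20L, 1, 2), seed = 1)$meta,
    n_perm = 50), "100")

  # planted group-specific hub: that node reaches small p
  net1 <- network_truth(atl, n_blocks = 2, block_size = 8, hub = TRUE,
                        hub_group = "VH")
  tr1 <- cohort_truth(atl, n_sites = 1, delta = 0, site_shift_sd = 0,
                      site_scale_sdlog = 0, loadings = net1$loadings,
                      seed = 2)
  # densities high enough that hub edges survive after the dense blocks
  # saturate the lower part of the sweep; averaging stabilizes the statistic
  hits <- vapply(1:4, function(s) {
    coh <- generate_cohort(atl, tr1, matrix(250L, 1, 2), seed = 900 + s)
    res <- suppressWarnings(residualize(coh$values, coh$meta))
    pt <- permutation_test_metrics(res, coh$meta,
                                   densities = seq(0.14, 0.20, 0.02),
                                   n_perm = 400, average_densities = TRUE,
                                   seed = s)
    pt$p_fdr[net1$hub_regions] <= 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("modularity bootstrap summarizes a seeded distribution", {
  atl <- generate_atlas(15, seed = 1)
  net <- network_truth(atl, n_blocks = 2, block_size = 8, hub = FALSE)
  tr <- cohort_truth(atl, n_sites = 1, delta = 0, site_shift_sd = 0,
                     site_scale_sdlog = 0, loadings = net$loadings, seed = 2)
  coh <- generate_cohort(atl, tr, matrix(80L, 1, 2), seed = 5)
  res <- suppressWarnings(residualize(coh$values, coh$meta))
  b1 <- bootstrap_modularity(res, coh$meta, "VH", reps = 60, seed = 9,
                             restarts = 10)
  b2 <- bootstrap_modularity(res, coh$meta, "VH", reps = 60, seed = 9,
                             restarts = 10)
  expect_identical(b1, b2)
  expect_true(b1$ci[1] <= b1$mean && b1$mean <= b1$ci[2])
  expect_warning(bootstrap_modularity(res, coh$meta, "VH", reps = 1,
                                      seed = 3, restarts = 5), "SD")
  # CI width shrinks with group size
  widths <- vapply(c(50L, 200L, 800L), function(n) {
    cohn <- generate_cohort(atl, tr, matrix(n, 1, 2), seed = 700 + n)
    rn <- suppressWarnings(residualize(cohn$values, cohn$meta))
    b <- bootstrap_modularity(rn, cohn$meta, "VH", reps = 100, seed = 1,
                              restarts = 10)
    diff(b$ci)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("difference-metric correlations respect algebraic identities", {
  set.seed(13)
  d <- rnorm(40)
  names(d) <- paste0("r", 1:40)
  out <- correlate_diff_metrics(d, list(lin = 2.5 * d), n_boot = 200,
                                seed = 3)
  expect_equal(out$r, 1, tolerance = 1e-12)
  out_neg <- correlate_diff_metrics(d, list(neg = -0.3 * d), n_boot = 200,
                                    seed = 3)
  expect_equal(out_neg$r, -1, tolerance = 1e-12)
  # standardized slope equals r for a simple regression
  md <- rnorm(40)
  names(md) <- names(d)
  o2 <- correlate_diff_metrics(d, list(m = md), n_boot = 100, seed = 5)
  expect_lt(abs(o2$slope * sd(md) / sd(d) - o2$r), 1e-12)
  expect_error(correlate_diff_metrics(d, list(z = rep(1, 40))),
               "zero-variance")
  # BH across metric families
  o3 <- correlate_diff_metrics(d, list(a = md, b = rnorm(40) + 0 * md,
                                       c = 0.5 * d + rnorm(40)),
                               n_boot = 50, seed = 7)
  expect_equal(o3$p_fdr, stats::p.adjust(o3$p, "BH"))
})

test_that("null difference-metric correlations are calibrated", {
  set.seed(17)
  rej <- replicate(300, {
    d <- rnorm(60)
    names(d) <- paste0("r", 1:60)
    md <- rnorm(60)
    names(md) <- names(d)
    correlate_diff_metrics(d, list(m = md), n_boot = 10, seed = 1)$p <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("edge-comparison type-I error is nominal under equal correlation", {
  out <- eval_edge_calibration(n_sim = 300, seed = 5)
  expect_gt(out$type1, 0.035)
  expect_lt(out$type1, 0.065)
})
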
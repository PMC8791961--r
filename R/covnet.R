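#' Residualize morphometrics on nuisance covariates
#'
#' Per-region OLS of the value on the declared covariates over the full
#' sample (both groups together), returning the residuals that structural
#' covariance is computed from. A Brown-Forsythe (median-centred) Levene
#' check of residual-variance homogeneity across groups is run per region
#' and reported as a warning summary plus an attribute — never an error.
#'
#' @param values Subjects x regions matrix.
#' @param meta Metadata with the covariates (default age + gender).
#' @param covariates Covariate columns.
#' @return Residual matrix (same shape), with attribute `levene` (per-region
#'   p-values) when a `group` column is present.
#' @export
residualize <- function(values, meta, covariates = c("age", "gender")) {
  assert_morph_table(values)
  meta <- align_meta(values, meta)
  Xc <- covariate_design(meta, covariates)
  X <- cbind(`(Intercept)` = 1, Xc)
  check_full_rank(X, "residualization design matrix")
  res <- stats::lm.fit(X, values)$residuals
  dimnames(res) <- dimnames(values)
  if ("group" %in% names(meta) && length(unique(meta$group)) > 1L) {
    grp <- factor(meta$group)
    lev_p <- vapply(seq_len(ncol(res)), function(j) {
      car::leveneTest(res[, j] ~ grp, center = stats::median)[1, "Pr(>F)"]
    }, numeric(1))
    names(lev_p) <- colnames(res)
    frac <- mean(lev_p < 0.05)
    if (frac > 0.2) {
      warning(sprintf(
        "variance homogeneity across groups questionable: %.0f%% of regions have Levene p < 0.05",
        100 * frac))
    }
    attr(res, "levene") <- lev_p
  }
  res
}

#' Group structural covariance matrix
#'
#' Pearson correlations of residualized morphometrics across the subjects of
#' one group: the structural covariance network in weighted form.
#'
#' @param residuals Subjects x regions residual matrix (see
#'   [residualize()]).
#' @param meta Metadata with `group`.
#' @param group Which group's subjects to use.
#' @return An object of class `cov_matrix`: `r` (regions x regions),
#'   `group_label`, `n_subjects`.
#' @export
covariance_matrix <- function(residuals, meta, group) {
  meta <- align_meta(residuals, meta)
  sel <- meta$group == group
  n <- sum(sel)
  if (n < 10L) stop("group '", group, "' has fewer than 10 subjects",
                    call. = FALSE)
  sub <- residuals[sel, , drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant region(s) within group '", group, "': ",
         paste(colnames(sub)[sds == 0], collapse = ", "), call. = FALSE)
  }
  out <- list(r = stats::cor(sub), group_label = group, n_subjects = n)
  class(out) <- "cov_matrix"
  out
}

#' Edge-wise comparison of two covariance matrices
#'
#' For every unordered region pair, Fisher z-transforms both correlations
#' and tests their difference with the two-independent-samples z statistic
#' \eqn{(z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}}, two-sided, with BH-FDR
#' over all pairs. Also reports `delta_r2` (r_a^2 - r_b^2); the display rule
#' used in circular plots (|delta_r2| > 0.3) is a reporting filter, applied
#' downstream, never here.
#'
#' @param cov_a,cov_b `cov_matrix` objects over the same regions from
#'   independent groups.
#' @return A data.frame with `region_a`, `region_b`, `r_a`, `r_b`, `z`,
#'   `p`, `p_fdr`, `delta_r2`; attribute `groups` records the labels.
#' @export
compare_edges <- function(cov_a, cov_b) {
  stopifnot(inherits(cov_a, "cov_matrix"), inherits(cov_b, "cov_matrix"))
  if (!identical(colnames(cov_a$r), colnames(cov_b$r))) {
    stop("covariance matrices are over different region sets", call. = FALSE)
  }
  R <- ncol(cov_a$r)
  ut <- which(upper.tri(cov_a$r), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  ra <- cov_a$r[ut]; rb <- cov_b$r[ut]
  clamp <- abs(ra) >= 1 | abs(rb) >= 1
  if (any(clamp)) {
    warning("correlation(s) at |r| = 1 clamped to 1 - 1e-12 for the Fisher ",
            "z transform")
    ra <- pmin(pmax(ra, -1 + 1e-12), 1 - 1e-12)
    rb <- pmin(pmax(rb, -1 + 1e-12), 1 - 1e-12)
  }
  se <- sqrt(1 / (cov_a$n_subjects - 3) + 1 / (cov_b$n_subjects - 3))
  z <- (atanh(ra) - atanh(rb)) / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(
    region_a = colnames(cov_a$r)[ut[, 1]],
    region_b = colnames(cov_a$r)[ut[, 2]],
    r_a = cov_a$r[ut], r_b = cov_b$r[ut],
    z = z, p = p, p_fdr = stats::p.adjust(p, "BH"),
    delta_r2 = cov_a$r[ut]^2 - cov_b$r[ut]^2,
    stringsAsFactors = FALSE
  )
  attr(out, "groups") <- c(a = cov_a$group_label, b = cov_b$group_label)
  out
}

#' Density-threshold a covariance matrix into a binary graph
#'
#' Keeps the k most positive off-diagonal correlations as undirected edges,
#' with k = round(density * R(R-1)/2) (round-half-even). Ties are broken by
#' deterministic lexicographic pair order; negative correlations are never
#' included, even if k is not met (then k = number of positive correlations,
#' with a warning).
#'
#' @param cov A `cov_matrix` object or a plain correlation matrix.
#' @param density Target edge density in (0, 1); values outside the usual
#'   sweep \[0.05, 0.20\] are allowed but warned about.
#' @return An object of class `thresholded_graph`: binary `adjacency`,
#'   `density`, `k`, `group_label`.
#' @export
threshold_graph <- function(cov, density) {
  r <- if (inherits(cov, "cov_matrix")) cov$r else cov
  group_label <- if (inherits(cov, "cov_matrix")) cov$group_label else NA
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)",
                                         call. = FALSE)
  if (density < 0.05 || density > 0.20) {
    warning("density ", density, " is outside the usual sweep [0.05, 0.20]")
  }
  R <- nrow(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]  # lexicographic pairs
  vals <- r[ut]
  k <- round(density * R * (R - 1) / 2)
  n_pos <- sum(vals > 0)
  if (n_pos < k) {
    warning("only ", n_pos, " positive correlations; k reduced from ", k)
    k <- n_pos
  }
  adj <- matrix(0L, R, R, dimnames = dimnames(r))
  if (k > 0) {
    ord <- order(-vals)  # stable: ties keep lexicographic order
    keep <- ut[ord[seq_len(k)], , drop = FALSE]
    adj[keep] <- 1L
    adj[keep[, c(2, 1), drop = FALSE]] <- 1L
  }
  out <- list(adjacency = adj, density = density, k = as.integer(k),
              group_label = group_label)
  class(out) <- "thresholded_graph"
  out
}

as_igraph <- function(graph) {
  adj <- if (inherits(graph, "thresholded_graph")) graph$adjacency else graph
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Node and graph metrics of a binary undirected graph
#'
#' Degree; betweenness centrality (unnormalized shortest-path counts with
#' fractional attribution over equal-length paths); nodal efficiency (mean
#' inverse shortest-path length to all other nodes, disconnected pairs
#' contributing 0); local efficiency (global efficiency of the subgraph
#' induced by each node's neighbours — the classic definition, distinct
#' from nodal efficiency); plus graph-level global efficiency and,
#' optionally, the Louvain modularity of the best partition.
#'
#' @param graph A `thresholded_graph` or binary adjacency matrix.
#' @param modularity Also run [detect_communities()] and report Q.
#' @param seed,restarts Passed to the community detection when
#'   `modularity = TRUE`.
#' @return A list with `nodes` (per-node data.frame), `global_efficiency`,
#'   and `modularity` (NULL unless requested).
#' @export
node_metrics <- function(graph, modularity = FALSE, seed = 1L,
                         restarts = 100L) {
  g <- as_igraph(graph)
  adj <- if (inherits(graph, "thresholded_graph")) graph$adjacency else graph
  R <- nrow(adj)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  nodal <- if (R > 1) rowSums(inv) / (R - 1) else rep(0, R)
  glob <- if (R > 1) sum(inv) / (R * (R - 1)) else 0
  local_eff <- vapply(seq_len(R), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2L) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    gs <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              diag = FALSE)
    ds <- igraph::distances(gs)
    invs <- 1 / ds
    diag(invs) <- 0
    invs[is.infinite(ds)] <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  nodes <- data.frame(
    region_id = rownames(adj) %||% as.character(seq_len(R)),
    degree = as.integer(rowSums(adj)),
    betweenness = igraph::betweenness(g, directed = FALSE),
    nodal_efficiency = nodal,
    local_efficiency = local_eff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  Q <- NULL
  if (modularity && igraph::ecount(g) > 0) {
    Q <- detect_communities(graph, seed = seed, restarts = restarts)$Q
  }
  list(nodes = nodes, global_efficiency = glob, modularity = Q)
}

#' Identify hubs from betweenness across a density sweep
#'
#' A node qualifies at one density when its betweenness centrality exceeds
#' the mean plus one standard deviation over all nodes at that density; it
#' is a hub when it qualifies at at least half (ceiling) of the densities.
#' With the standard sweep 0.05-0.20 in steps of 0.01 (16 densities) the
#' qualification threshold is 8. At a density where betweenness has zero
#' variance, no node qualifies.
#'
#' @param betweenness Nodes x densities matrix (rownames = region ids).
#' @return A list with `hubs` (region ids), `qualified` (logical matrix),
#'   `n_qualified` per node, and `threshold`.
#' @export
identify_hubs <- function(betweenness) {
  stopifnot(is.matrix(betweenness))
  if (ncol(betweenness) < 2L) stop("need metrics at >= 2 densities",
                                   call. = FALSE)
  qual <- apply(betweenness, 2, function(b) {
    s <- stats::sd(b)
    if (s == 0) rep(FALSE, length(b)) else b > mean(b) + s
  })
  thr <- ceiling(ncol(betweenness) / 2)
  n_q <- rowSums(qual)
  ids <- rownames(betweenness) %||% as.character(seq_len(nrow(betweenness)))
  list(hubs = ids[n_q >= thr],
       qualified = qual, n_qualified = n_q, threshold = thr)
}

# Betweenness of one covariance matrix across a density sweep.
betweenness_sweep <- function(cov, densities = seq(0.05, 0.20, by = 0.01)) {
  mats <- vapply(densities, function(d) {
    suppressWarnings(
      igraph::betweenness(as_igraph(threshold_graph(cov, d)),
                          directed = FALSE))
  }, numeric(if (inherits(cov, "cov_matrix")) ncol(cov$r) else ncol(cov)))
  rownames(mats) <- if (inherits(cov, "cov_matrix")) colnames(cov$r) else
    colnames(cov)
  colnames(mats) <- paste0("d", densities)
  mats
}

#' Louvain community detection with restarts
#'
#' Runs the Louvain algorithm `restarts` times under a fixed seed and keeps
#' the partition with the highest Newman-Girvan modularity. Community labels
#' are canonicalized by descending community size (ties by smallest member
#' index) so partitions are comparable across runs.
#'
#' @param graph A `thresholded_graph` or binary adjacency matrix with at
#'   least one edge.
#' @param seed Integer seed (Louvain is stochastic).
#' @param restarts Number of restarts.
#' @return A list with `membership` (named integer vector), `Q`, `seed`,
#'   `restarts`.
#' @export
detect_communities <- function(graph, seed = 1L, restarts = 100L) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0) stop("graph has no edges", call. = FALSE)
  best <- with_seed(seed, {
    best_q <- -Inf; best_m <- NULL
    for (i in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        best_m <- igraph::membership(cl)
      }
    }
    list(Q = best_q, membership = best_m)
  })
  m <- as.integer(best$membership)
  sizes <- table(m)
  first_member <- vapply(names(sizes), function(lb) min(which(m == lb)),
                         numeric(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  m2 <- relabel[as.character(m)]
  names(m2) <- igraph::V(g)$name %||% as.character(seq_along(m))
  list(membership = m2, Q = best$Q, seed = as.integer(seed),
       restarts = as.integer(restarts))
}

metric_fun <- function(metric) {
  switch(metric,
    degree = function(tg) as.numeric(rowSums(tg$adjacency)),
    betweenness = function(tg) {
      igraph::betweenness(as_igraph(tg), directed = FALSE)
    },
    nodal_efficiency = function(tg) {
      d <- igraph::distances(as_igraph(tg))
      inv <- 1 / d
      diag(inv) <- 0
      inv[is.infinite(d)] <- 0
      rowSums(inv) / (nrow(d) - 1)
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

# Per-node metric stack for one group: nodes x densities.
metric_stack <- function(residuals, sel, densities, metric) {
  r <- stats::cor(residuals[sel, , drop = FALSE])
  f <- metric_fun(metric)
  vapply(densities, function(d) {
    f(suppressWarnings(threshold_graph(r, d)))
  }, numeric(ncol(residuals)))
}

#' Permutation test of between-group node-metric differences
#'
#' The observed statistic is the per-node difference (group a minus group b)
#' of a graph metric computed from each group's thresholded covariance
#' network, per density or averaged over the sweep. The null is built by
#' shuffling group labels and rebuilding everything (covariance, threshold,
#' metric) per permutation;
#' \eqn{p = (1 + \#\{|null| \ge |obs|\})/(1 + n_{perm})}, BH-FDR over nodes
#' (and densities in per-density mode).
#'
#' @param residuals Subjects x regions residual matrix.
#' @param meta Metadata with `group`.
#' @param group_a,group_b Labels; the difference is a minus b.
#' @param metric `"betweenness"`, `"degree"` or `"nodal_efficiency"`.
#' @param densities Density sweep.
#' @param n_perm Permutations (>= 100; fewer is refused).
#' @param average_densities Average the metric over the sweep before
#'   differencing.
#' @param seed Integer seed.
#' @return A list with `observed` (nodes x densities matrix, or vector when
#'   averaged), `p`, `p_fdr` (same shape), `metric`, `densities`, `n_perm`.
#' @export
permutation_test_metrics <- function(residuals, meta, group_a = "VH",
                                     group_b = "noVH",
                                     metric = "betweenness",
                                     densities = seq(0.05, 0.20, by = 0.01),
                                     n_perm = 1000L,
                                     average_densities = FALSE,
                                     seed = 1L) {
  if (n_perm < 100L) stop("n_perm below 100 refused: p-values too unstable",
                          call. = FALSE)
  meta <- align_meta(residuals, meta)
  ga <- meta$group == group_a
  gb <- meta$group == group_b
  if (!any(ga) || !any(gb)) stop("both groups must be present", call. = FALSE)
  use <- ga | gb
  residuals <- residuals[use, , drop = FALSE]
  is_a <- ga[use]
  n_a <- sum(is_a)
  stat <- function(sel_a) {
    m <- metric_stack(residuals, sel_a, densities, metric) -
      metric_stack(residuals, !sel_a, densities, metric)
    if (average_densities) rowMeans(m) else m
  }
  obs <- stat(is_a)
  exceed <- obs * 0
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      sel <- logical(length(is_a))
      sel[sample.int(length(is_a), n_a)] <- TRUE
      null_b <- stat(sel)
      exceed <- exceed + (abs(null_b) >= abs(obs))
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p_fdr <- p
  p_fdr[] <- stats::p.adjust(p, "BH")
  if (is.matrix(obs)) {
    dimnames(obs) <- list(colnames(residuals), paste0("d", densities))
    dimnames(p) <- dimnames(p_fdr) <- dimnames(obs)
  } else {
    names(obs) <- names(p) <- names(p_fdr) <- colnames(residuals)
  }
  list(observed = obs, p = p, p_fdr = p_fdr, metric = metric,
       densities = densities, n_perm = as.integer(n_perm),
       groups = c(a = group_a, b = group_b))
}

#' Bootstrap distribution of network modularity
#'
#' Resamples subjects with replacement within one group, rebuilds the
#' covariance matrix, thresholds at the given density, and records the
#' Louvain modularity of the best partition, summarizing the distribution
#' with mean, SD and a percentile interval.
#'
#' @param residuals Subjects x regions residual matrix.
#' @param meta Metadata with `group`.
#' @param group Group to resample.
#' @param density Graph density (study convention: 0.13).
#' @param reps Bootstrap replicates.
#' @param level CI level.
#' @param seed Integer seed.
#' @param restarts Louvain restarts per replicate.
#' @return A list with `mean`, `sd`, `ci`, `q_values`, `density`, `reps`.
#' @export
bootstrap_modularity <- function(residuals, meta, group, density = 0.13,
                                 reps = 1000L, level = 0.95, seed = 1L,
                                 restarts = 20L) {
  meta <- align_meta(residuals, meta)
  sel <- which(meta$group == group)
  if (length(sel) < 10L) stop("group has fewer than 10 subjects",
                              call. = FALSE)
  qs <- with_seed(seed, {
    child <- sample.int(.Machine$integer.max - 1L, reps)
    vapply(seq_len(reps), function(b) {
      ix <- sample(sel, length(sel), replace = TRUE)
      r <- stats::cor(residuals[ix, , drop = FALSE])
      r[is.na(r)] <- 0  # a resample can make a region constant
      tg <- suppressWarnings(threshold_graph(r, density))
      detect_communities(tg, seed = child[b], restarts = restarts)$Q
    }, numeric(1))
  })
  sd_q <- if (reps > 1L) stats::sd(qs) else {
    warning("reps = 1: SD undefined, reported as 0")
    0
  }
  list(mean = mean(qs), sd = sd_q,
       ci = stats::quantile(qs, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE),
       q_values = qs, density = density, reps = as.integer(reps))
}

#' Correlate a difference map with graph-metric differences
#'
#' Pearson correlation (two-sided t p-value) of the per-region morphometric
#' difference of means with one or more per-region graph-metric differences,
#' BH-corrected across the metric families tested, plus an OLS of the
#' morphometric difference on each metric difference with a seeded
#' percentile bootstrap CI for the slope.
#'
#' @param diff A `difference_map` data.frame or named numeric vector.
#' @param metric_diffs Named list of per-region metric-difference vectors
#'   (or one vector).
#' @param n_boot Bootstrap resamples.
#' @param level CI level.
#' @param seed Integer seed.
#' @return A data.frame with one row per metric: `metric`, `r`, `p`,
#'   `p_fdr`, `slope`, `ci_lo`, `ci_hi`, `n`.
#' @export
correlate_diff_metrics <- function(diff, metric_diffs, n_boot = 10000L,
                                   level = 0.95, seed = 1L) {
  if (inherits(diff, "difference_map") || is.data.frame(diff)) {
    d <- stats::setNames(diff$diff, diff$region_id)
  } else d <- diff
  if (!is.list(metric_diffs)) metric_diffs <- list(metric = metric_diffs)
  seeds <- derive_seeds(seed, names(metric_diffs))
  rows <- lapply(names(metric_diffs), function(nm) {
    md <- metric_diffs[[nm]]
    if (!is.null(names(md)) && !is.null(names(d))) {
      common <- intersect(names(d), names(md))
      if (length(common) == 0L) stop("no aligned regions for metric ", nm,
                                     call. = FALSE)
      x <- md[common]; y <- d[common]
    } else {
      stopifnot(length(md) == length(d))
      x <- md; y <- d
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero-variance input for metric ", nm, call. = FALSE)
    }
    ct <- stats::cor.test(x, y)
    n <- length(x)
    fit <- stats::lm(y ~ x)
    ci <- with_seed(seeds[[nm]], {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
      xb <- matrix(x[idx], n, n_boot); yb <- matrix(y[idx], n, n_boot)
      mx <- colMeans(xb); my <- colMeans(yb)
      slopes <- (colSums(xb * yb) - n * mx * my) /
        (colSums(xb^2) - n * mx^2)
      slopes <- slopes[is.finite(slopes)]
      stats::quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE)
    })
    data.frame(metric = nm, r = unname(ct$estimate), p = ct$p.value,
               slope = unname(stats::coef(fit)[2]),
               ci_lo = ci[1], ci_hi = ci[2], n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, "BH")
  out[, c("metric", "r", "p", "p_fdr", "slope", "ci_lo", "ci_hi", "n")]
}
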
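#' Construct the ground truth for a synthetic multi-site cohort
#'
#' Bundles every parameter of the generative model used by
#' [generate_cohort()]: per-region baselines, a region-sparse group effect,
#' per-site additive and multiplicative scanner effects, covariate slopes,
#' group-specific latent-factor loadings (which induce inter-regional
#' covariance, planted hubs and communities), and residual noise.
#'
#' The generative model for subject j in site s, group g, region r is
#' \deqn{y_{jr} = base_r + \sum_c \beta_{cr} (x_{cj} - center_c) +
#'   \delta_r 1[g = VH] + (\Lambda_g f_j)_r + shift_{sr} +
#'   scale_{sr} \, \sigma_r \varepsilon_{jr}}
#' with factor scores \eqn{f_j \sim N(0, I)} and
#' \eqn{\varepsilon \sim N(0, 1)}. The multiplicative site effect scales the
#' residual only, matching the location-scale model that empirical-Bayes
#' harmonisation assumes.
#'
#' Site effects are drawn here (not in [generate_cohort()]) so a single truth
#' object pins down the population; the cohort generator then only draws
#' subjects.
#'
#' @param atlas Atlas whose regions the truth is defined over.
#' @param n_sites Number of scanning sites.
#' @param delta Named per-region group effect in measure units (VH minus
#'   noVH); or a single number applied to `delta_regions`. Default plants
#'   cortical thinning of `-0.3 * noise_sd` in 10 mirror-paired regions
#'   (20 regions).
#' @param delta_regions Region ids receiving `delta` when `delta` is scalar.
#' @param site_shift_sd SD (measure units) of additive site effects; 0 turns
#'   them off.
#' @param site_scale_sdlog SD of log multiplicative site effects; 0 gives all
#'   scales equal to 1.
#' @param covariate_betas Named list of per-region slope vectors (or scalars)
#'   for `age` (units/year), `gender` (units for female), `tiv` (units/mm^3).
#'   Defaults are small realistic thickness effects.
#' @param loadings Either `NULL` (no latent covariance), a regions x k
#'   loading matrix shared by both groups, or a list with elements `VH` and
#'   `noVH` of regions x k matrices.
#' @param hub_regions,community_labels Optional planted network ground truth
#'   carried along for recovery experiments (see [network_truth()]).
#' @param noise_sd Per-region residual SD (scalar or named vector), measure
#'   units.
#' @param baseline Per-region baseline mean (scalar or named vector).
#' @param measure One of "thickness", "area", "volume".
#' @param seed Integer seed for the site-effect draws.
#' @return A list of class `cohort_truth`.
#' @examples
#' atl <- generate_atlas(10, seed = 1)
#' tr <- cohort_truth(atl, n_sites = 2, seed = 3)
#' round(tr$delta[tr$delta != 0], 3)
#' @export
cohort_truth <- function(atlas,
                         n_sites = 3L,
                         delta = NULL,
                         delta_regions = NULL,
                         site_shift_sd = 0.1,
                         site_scale_sdlog = 0.15,
                         covariate_betas = NULL,
                         loadings = NULL,
                         hub_regions = character(),
                         community_labels = NULL,
                         noise_sd = 0.15,
                         baseline = 2.5,
                         measure = c("thickness", "area", "volume"),
                         seed = 1L) {
  validate_atlas(atlas, symmetric = FALSE)
  measure <- match.arg(measure)
  n_sites <- assert_count(n_sites, "n_sites", min = 1L)
  regions <- atlas$region_id
  R <- length(regions)

  expand <- function(x, name) {
    if (length(x) == 1L) x <- stats::setNames(rep(as.numeric(x), R), regions)
    if (is.null(names(x)) || !all(regions %in% names(x))) {
      stop(sprintf("`%s` must be scalar or named over all atlas regions", name),
           call. = FALSE)
    }
    x[regions]
  }
  noise_sd <- expand(noise_sd, "noise_sd")
  if (any(noise_sd <= 0)) stop("noise_sd must be positive", call. = FALSE)
  baseline <- expand(baseline, "baseline")

  # Group effect: default = thinning of 0.3 residual SD in 10 mirrored pairs.
  if (is.null(delta)) {
    if (is.null(delta_regions)) {
      n_half <- min(10L, sum(atlas$hemisphere == "L"))
      lefts <- regions[atlas$hemisphere == "L"][seq_len(n_half)]
      delta_regions <- c(lefts, atlas$mirror_of[match(lefts, regions)])
    }
    delta <- stats::setNames(rep(0, R), regions)
    delta[delta_regions] <- -0.3 * noise_sd[delta_regions]
  } else if (length(delta) == 1L && !is.null(delta_regions)) {
    d <- stats::setNames(rep(0, R), regions)
    d[delta_regions] <- as.numeric(delta)
    delta <- d
  } else {
    delta <- expand(delta, "delta")
  }

  if (is.null(covariate_betas)) {
    covariate_betas <- list(age = -0.008, gender = -0.02, tiv = 1.5e-7)
  }
  covariate_betas <- lapply(stats::setNames(names(covariate_betas),
                                            names(covariate_betas)),
                            function(nm) expand(covariate_betas[[nm]], nm))

  if (!is.null(loadings) && !is.list(loadings)) {
    loadings <- list(VH = loadings, noVH = loadings)
  }
  if (!is.null(loadings)) {
    for (g in names(loadings)) {
      L <- loadings[[g]]
      if (!is.matrix(L) || nrow(L) != R) {
        stop("loadings must be regions x k matrices over all atlas regions",
             call. = FALSE)
      }
      rownames(L) <- regions
      loadings[[g]] <- L
    }
  }

  sites <- paste0("site", seq_len(n_sites))
  eff <- with_seed(seed, list(
    shift = matrix(stats::rnorm(n_sites * R, 0, site_shift_sd),
                   n_sites, R, dimnames = list(sites, regions)),
    scale = matrix(exp(stats::rnorm(n_sites * R, 0, site_scale_sdlog)),
                   n_sites, R, dimnames = list(sites, regions))
  ))
  # Identifiability of the planted effects: centre shifts and log-scales
  # across sites so "site 1" is not systematically the reference.
  if (n_sites > 1L) {
    eff$shift <- sweep(eff$shift, 2, colMeans(eff$shift))
    eff$scale <- sweep(eff$scale, 2, exp(colMeans(log(eff$scale))), "/")
  }
  if (site_shift_sd == 0) eff$shift[] <- 0
  if (site_scale_sdlog == 0) eff$scale[] <- 1

  out <- list(
    regions = regions, sites = sites, measure = measure,
    baseline = baseline, delta = delta,
    site_shift = eff$shift, site_scale = eff$scale,
    covariate_betas = covariate_betas,
    covariate_centers = c(age = 66, gender = 0, tiv = 1.45e6),
    loadings = loadings,
    hub_regions = hub_regions, community_labels = community_labels,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(out) <- "cohort_truth"
  out
}

#' Plant a block-community covariance structure with optional bridge hubs
#'
#' Builds latent-factor loading matrices that induce a known network: each
#' block of regions loads on its own factor (forming a dense community after
#' density thresholding), and an optional hub region loads on every block
#' factor, making it the sole bridge between communities — the archetype of a
#' high-betweenness node.
#'
#' @param atlas Atlas defining the region set.
#' @param n_blocks Number of planted communities.
#' @param block_size Regions per block (taken in atlas order; blocks never
#'   overlap the hub).
#' @param loading Factor loading of block members (measure units per unit
#'   factor score). The default, equal to the default residual SD of
#'   [cohort_truth()], gives a within-community residual correlation of 0.5
#'   — the magnitude typical of structural covariance blocks.
#' @param hub Logical: plant a bridge hub after the blocks?
#' @param hub_loading Loading of the hub on every block factor; defaults to
#'   the community loading (a bridge as strong as the communities it
#'   links).
#' @param hub_group `"both"`, `"VH"` or `"noVH"`: which group's loading
#'   matrix carries the hub (a single-group hub gives a true between-group
#'   network difference).
#' @return A list with `loadings` (per group), `hub_regions`, and
#'   `community_labels`, ready to splice into [cohort_truth()].
#' @export
network_truth <- function(atlas, n_blocks = 2L, block_size = 10L,
                          loading = 0.15, hub = TRUE, hub_loading = loading,
                          hub_group = c("both", "VH", "noVH")) {
  hub_group <- match.arg(hub_group)
  regions <- atlas$region_id
  R <- length(regions)
  need <- n_blocks * block_size + as.integer(hub)
  if (R < need) stop("atlas too small for the requested block structure",
                     call. = FALSE)
  L <- matrix(0, R, n_blocks, dimnames = list(regions, NULL))
  labels <- stats::setNames(rep(0L, R), regions)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):(b * block_size)
    L[idx, b] <- loading
    labels[idx] <- b
  }
  hub_regions <- character()
  L_hub <- L
  if (hub) {
    h <- n_blocks * block_size + 1L
    L_hub[h, ] <- hub_loading
    hub_regions <- regions[h]
  }
  loadings <- switch(hub_group,
    both = list(VH = L_hub, noVH = L_hub),
    VH = list(VH = L_hub, noVH = L),
    noVH = list(VH = L, noVH = L_hub)
  )
  list(loadings = loadings, hub_regions = hub_regions,
       community_labels = labels)
}

#' Generate a synthetic multi-site cohort with known ground truth
#'
#' Draws subject metadata (site, group, age, gender, TIV, clinical scores)
#' and a morphometric table from the generative model described in
#' [cohort_truth()]. Deterministic given `seed`.
#'
#' Covariate distributions: age ~ Normal(66, 8.5) years truncated to
#' \[40, 90\]; TIV ~ Normal(1.45e6, 1.5e5) mm^3; gender ~ Bernoulli(0.4)
#' female; LED ~ Normal(550, 250) mg truncated at 0; MMSE integer 24–30;
#' UPDRS-III ~ Normal(25, 11) truncated \[0, 132\]; disease onset ~
#' Normal(5.5, 3) years truncated \[0.5, 25\]. The NPI hallucination subscale
#' (frequency x severity) has no published distribution: VH subjects draw
#' from a discrete distribution on the attainable products
#' \{1,2,3,4,6,8,9,12\}, noVH subjects score 0, and a configurable fraction
#' of values is set missing.
#'
#' @param atlas Atlas the truth was built over.
#' @param truth A [cohort_truth()] object.
#' @param n_per_group_per_site Subjects per group per site: a single count,
#'   or a sites x 2 matrix / list with columns (VH, noVH).
#' @param seed Integer seed.
#' @param npi_missing_rate Fraction of NPI scores set missing at random.
#' @return A list with `values` (subjects x regions matrix, measure attribute
#'   set) and `meta` (data.frame of subject metadata).
#' @examples
#' atl <- generate_atlas(10, seed = 1)
#' tr <- cohort_truth(atl, n_sites = 2, seed = 3)
#' coh <- generate_cohort(atl, tr, n_per_group_per_site = 20, seed = 7)
#' dim(coh$values); table(coh$meta$site, coh$meta$group)
#' @export
generate_cohort <- function(atlas, truth, n_per_group_per_site, seed = 1L,
                            npi_missing_rate = 0.1) {
  validate_atlas(atlas, symmetric = FALSE)
  stopifnot(inherits(truth, "cohort_truth"))
  if (!identical(truth$regions, atlas$region_id)) {
    stop("truth regions do not match the atlas", call. = FALSE)
  }
  S <- length(truth$sites)
  if (is.matrix(n_per_group_per_site)) {
    n_tab <- n_per_group_per_site
  } else if (length(n_per_group_per_site) == 1L) {
    n_tab <- matrix(as.integer(n_per_group_per_site), S, 2)
  } else {
    stop("n_per_group_per_site must be a count or a sites x 2 matrix",
         call. = FALSE)
  }
  colnames(n_tab) <- c("VH", "noVH")
  if (any(n_tab < 2L)) stop("need >= 2 subjects per group per site",
                            call. = FALSE)

  if (!is.null(truth$loadings)) {
    for (g in names(truth$loadings)) {
      L <- truth$loadings[[g]]
      # implied covariance L L' + diag is PSD by construction; guard anyway
      if (any(!is.finite(L))) stop("invalid truth: non-finite loadings",
                                   call. = FALSE)
    }
  }

  regions <- truth$regions
  R <- length(regions)
  N <- sum(n_tab)

  with_seed(seed, {
    site <- rep(rep(truth$sites, 2), times = c(n_tab[, "VH"], n_tab[, "noVH"]))
    group <- rep(rep(c("VH", "noVH"), each = S),
                 times = c(n_tab[, "VH"], n_tab[, "noVH"]))
    ord <- order(match(site, truth$sites), group != "VH")
    site <- site[ord]; group <- group[ord]

    rtrunc <- function(n, mean, sd, lo, hi) {
      pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
    }
    age <- rtrunc(N, 66, 8.5, 40, 90)
    gender <- ifelse(stats::runif(N) < 0.4, "F", "M")
    tiv <- stats::rnorm(N, 1.45e6, 1.5e5)
    led <- pmax(0, stats::rnorm(N, 550, 250))
    mmse <- pmin(30L, pmax(24L, round(stats::rnorm(N, 28, 1.6))))
    updrs3 <- rtrunc(N, 25, 11, 0, 132)
    onset <- rtrunc(N, 5.5, 3, 0.5, 25)
    npi_support <- c(1, 2, 3, 4, 6, 8, 9, 12)
    npi_prob <- c(0.22, 0.18, 0.14, 0.14, 0.12, 0.08, 0.07, 0.05)
    npi <- ifelse(group == "VH",
                  sample(npi_support, N, replace = TRUE, prob = npi_prob), 0)
    if (npi_missing_rate > 0) {
      npi[stats::runif(N) < npi_missing_rate] <- NA_real_
    }

    meta <- data.frame(
      subject_id = sprintf("sub%04d", seq_len(N)),
      site = site, group = group,
      age = age, gender = gender, tiv = tiv, led = led,
      mmse = mmse, updrs3 = updrs3, onset = onset, npi = npi,
      stringsAsFactors = FALSE
    )

    centers <- truth$covariate_centers
    cov_term <- matrix(0, N, R)
    for (nm in names(truth$covariate_betas)) {
      x <- switch(nm,
                  gender = as.numeric(gender == "F"),
                  meta[[nm]] - (centers[nm] %||% 0))
      if (is.null(x)) next
      cov_term <- cov_term + outer(as.numeric(x), truth$covariate_betas[[nm]])
    }

    latent <- matrix(0, N, R)
    if (!is.null(truth$loadings)) {
      k <- ncol(truth$loadings[[1]])
      f <- matrix(stats::rnorm(N * k), N, k)
      for (g in c("VH", "noVH")) {
        idx <- which(group == g)
        Lg <- truth$loadings[[g]] %||% truth$loadings[[1]]
        latent[idx, ] <- f[idx, , drop = FALSE] %*% t(Lg)
      }
    }

    s_idx <- match(site, truth$sites)
    eps <- matrix(stats::rnorm(N * R), N, R)
    noise <- truth$site_scale[s_idx, , drop = FALSE] *
      sweep(eps, 2, truth$noise_sd, "*")

    values <- matrix(rep(truth$baseline, each = N), N, R) +
      cov_term +
      outer(as.numeric(group == "VH"), truth$delta) +
      latent +
      truth$site_shift[s_idx, , drop = FALSE] +
      noise
    dimnames(values) <- list(meta$subject_id, regions)
    attr(values, "measure") <- truth$measure

    list(values = values, meta = meta)
  })
}
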
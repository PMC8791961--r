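#' Load and validate the inputs of a full analysis run
#'
#' Accepts a configuration list (or the path of a YAML file holding one)
#' and returns a validated in-memory bundle. The configuration either
#' references CSV inputs (`morphometrics`, `meta`, `atlas`, optional
#' `receptor_maps`) or carries a `synthetic` block describing a cohort to
#' generate (atlas size, sites, group sizes, receptor maps with target
#' correlations).
#'
#' Cross-checks performed: metadata covers every subject; morphometric
#' regions all exist in the atlas; receptor maps cover atlas regions.
#' Failures name the offending column, subject or region.
#'
#' @param config A list or a YAML file path. Recognized top-level fields:
#'   `inputs` (paths), `synthetic` (generator spec), `covariates`,
#'   `network_covariates`, `fdr`, `densities` (`from`, `to`, `by`),
#'   `n_spins`, `n_perm`, `n_boot`, `pca_regions`, `seed`, `out`.
#' @return A list of class `pipeline_bundle`: `values`, `meta`, `atlas`,
#'   `receptor_maps` (named list), `truth` (synthetic runs only), and the
#'   resolved `config`.
#' @export
load_inputs <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- resolve_config(config)
  seeds <- derive_seeds(cfg$seed, c("atlas", "truth", "cohort", "receptors",
                                    "spins", "perm", "boot"))
  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    atlas <- generate_atlas(syn$n_per_hemisphere %||% 34L,
                            seed = seeds[["atlas"]])
    net <- NULL
    if (isTRUE(syn$plant_network)) {
      net <- network_truth(atlas,
                           n_blocks = syn$n_blocks %||% 2L,
                           block_size = syn$block_size %||% 10L,
                           hub_group = syn$hub_group %||% "both")
    }
    truth <- cohort_truth(
      atlas, n_sites = syn$n_sites %||% 3L,
      site_shift_sd = syn$site_shift_sd %||% 0.1,
      site_scale_sdlog = syn$site_scale_sdlog %||% 0.15,
      loadings = net$loadings,
      hub_regions = net$hub_regions %||% character(),
      community_labels = net$community_labels,
      seed = seeds[["truth"]]
    )
    coh <- generate_cohort(atlas, truth,
                           syn$n_per_group_per_site %||% 33L,
                           seed = seeds[["cohort"]])
    values <- coh$values
    meta <- coh$meta
    receptor_maps <- list()
    rec_specs <- syn$receptors %||%
      list(list(label = "synthetic_receptor", rho = 0.5))
    dm <- compute_difference_map(values, meta)
    target <- stats::setNames(dm$diff, dm$region_id)
    rseeds <- derive_seeds(seeds[["receptors"]],
                           vapply(rec_specs, function(s)
                             s$label %||% "receptor", character(1)))
    for (i in seq_along(rec_specs)) {
      s <- rec_specs[[i]]
      lab <- s$label %||% paste0("receptor", i)
      receptor_maps[[lab]] <- generate_receptor_map(
        atlas, smoothness = s$smoothness %||% 20,
        target = if (!is.null(s$rho)) target else NULL,
        rho = s$rho, seed = rseeds[[i]], receptor_label = lab)
    }
  } else {
    inp <- cfg$inputs
    if (is.null(inp$morphometrics) || is.null(inp$meta) ||
        is.null(inp$atlas)) {
      stop("config$inputs needs morphometrics, meta and atlas paths",
           call. = FALSE)
    }
    values <- read_morph_csv(inp$morphometrics,
                             measure = inp$measure %||% "thickness")
    meta <- read_meta_csv(inp$meta)
    atlas <- read_atlas_csv(inp$atlas)
    receptor_maps <- list()
    for (lab in names(inp$receptor_maps %||% list())) {
      receptor_maps[[lab]] <- read_receptor_csv(inp$receptor_maps[[lab]],
                                                receptor_label = lab)
    }
  }
  miss_sub <- setdiff(rownames(values), meta$subject_id)
  if (length(miss_sub)) {
    stop("subject(s) in morphometrics but not metadata: ",
         paste(utils::head(miss_sub, 5), collapse = ", "), call. = FALSE)
  }
  bad_reg <- setdiff(colnames(values), atlas$region_id)
  if (length(bad_reg)) {
    stop("region(s) in morphometrics but not atlas: ",
         paste(utils::head(bad_reg, 5), collapse = ", "), call. = FALSE)
  }
  for (lab in names(receptor_maps)) {
    gap <- setdiff(colnames(values), receptor_maps[[lab]]$region_id)
    if (length(gap)) {
      stop("receptor map '", lab, "' missing region(s): ",
           paste(utils::head(gap, 5), collapse = ", "), call. = FALSE)
    }
  }
  out <- list(values = values, meta = meta, atlas = atlas,
              receptor_maps = receptor_maps, truth = truth,
              config = cfg, seeds = seeds)
  class(out) <- "pipeline_bundle"
  out
}

resolve_config <- function(config) {
  dens <- config$densities %||% list(from = 0.05, to = 0.20, by = 0.01)
  list(
    inputs = config$inputs,
    synthetic = config$synthetic,
    covariates = config$covariates %||% c("age", "gender", "tiv"),
    network_covariates = config$network_covariates %||% c("age", "gender"),
    fdr = config$fdr %||% 0.05,
    densities = seq(dens$from, dens$to, by = dens$by),
    display_density = config$display_density %||% 0.13,
    n_spins = config$n_spins %||% 1000L,
    n_perm = config$n_perm %||% 1000L,
    n_boot = config$n_boot %||% 1000L,
    louvain_restarts = config$louvain_restarts %||% 100L,
    seed = config$seed %||% 1L,
    out = config$out
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages end-to-end on a validated bundle: harmonisation
#' (empirical-Bayes site adjustment, with before/after site-effect audit),
#' region screening + MANCOVA on the survivors, the group difference map,
#' receptor associations (regression with influence diagnostics and
#' bootstrap CI, plus spin-permutation correlation p) per receptor map, PCA
#' of the flagged regions, and structural covariance networks (edge
#' comparison, hubs, communities, modularity bootstrap). Deterministic
#' given the config seed; every child seed is recorded in the report.
#'
#' @param config A configuration list / YAML path (see [load_inputs()]) or
#'   an already-loaded `pipeline_bundle`.
#' @return A `pipeline_report` list with one entry per stage plus `config`
#'   and `seeds`. When `config$out` is set, CSV/JSON artefacts are written
#'   there as well.
#' @export
run_pipeline <- function(config) {
  bundle <- if (inherits(config, "pipeline_bundle")) config else
    load_inputs(config)
  cfg <- bundle$config
  seeds <- bundle$seeds
  values <- bundle$values
  meta <- bundle$meta
  report <- list(config = cfg, seeds = as.list(seeds), warnings = list())
  note <- function(stage, w) {
    report$warnings[[stage]] <<- c(report$warnings[[stage]], w)
  }
  grab <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  # 1. harmonisation
  harm <- grab("harmonise", {
    pre <- site_effect_report(values, meta)
    fit <- fit_combat(values, meta, biological_covariates = cfg$covariates)
    adj <- apply_combat(fit, values, meta)
    post <- site_effect_report(adj, meta)
    list(summary = list(eta2_pre = mean(pre$eta2),
                        eta2_post = mean(post$eta2),
                        converged = fit$converged, n_iter = fit$n_iter),
         adj = adj)
  })
  report$harmonisation <- harm$summary
  adj <- harm$adj

  # 2. screening + MANCOVA
  report$screening <- grab("screen", {
    scr <- screen_regions_anova(adj, meta, covariates = cfg$covariates,
                                q = cfg$fdr)
    flagged <- scr$region_id[scr$flagged]
    manc <- if (length(flagged) >= 1 &&
                nrow(adj) > length(flagged) + length(cfg$covariates) + 2) {
      fit_mancova(adj, meta, flagged, covariates = cfg$covariates)
    } else NULL
    list(table = scr, flagged = flagged,
         mancova_multivariate = manc$multivariate,
         mancova_pairwise = manc$pairwise)
  })
  flagged <- report$screening$flagged

  # 3. difference map
  dm <- compute_difference_map(adj, meta)
  report$difference_map <- dm

  # 4. receptor associations
  report$receptor <- grab("receptor", if (length(bundle$receptor_maps) == 0) {
    list()
  } else {
    spins <- generate_spin_permutations(bundle$atlas, cfg$n_spins,
                                        seed = seeds[["spins"]])
    rseeds <- derive_seeds(seeds[["boot"]], names(bundle$receptor_maps))
    lapply(bundle$receptor_maps, function(map) {
      lab <- attr(map, "receptor_label")
      subsets <- list(all = NULL)
      if (length(flagged) >= 8) subsets$significant <- flagged
      nonsig <- setdiff(dm$region_id, flagged)
      if (length(nonsig) >= 8 && length(flagged) >= 8) {
        subsets$nonsignificant <- nonsig
      }
      fits <- lapply(names(subsets), function(sl) {
        al <- align_receptor_map(map, dm, atlas = bundle$atlas,
                                 subset = subsets[[sl]])
        fit_receptor_regression(
          stats::setNames(al$diff, al$region_id), al$bp, subset_label = sl,
          n_boot = cfg$n_boot, seed = rseeds[[lab]])
      })
      names(fits) <- names(subsets)
      al_all <- align_receptor_map(map, dm, atlas = bundle$atlas)
      sct <- spin_correlation_test(
        stats::setNames(al_all$diff, al_all$region_id),
        stats::setNames(al_all$bp, al_all$region_id), spins)
      list(fits = fits, spin = sct[c("r_obs", "p_spin", "n_spins")])
    })
  })  # end receptor grab (if/else value)

  # 5. PCA on flagged regions
  report$pca <- grab("pca", if (length(flagged) < 2) NULL else {
    res <- run_pca(adj[, flagged, drop = FALSE])
    sel <- select_components(res)
    list(eigenvalues = res$eigenvalues, n_retained = sel$n_retained,
         variance_pct = 100 * res$variance_fraction[
           seq_len(sel$n_retained)],
         top_contributors = sel$top_contributors, scree = sel$scree)
  })

  # 6. covariance networks
  report$network <- grab("covnet", {
    res <- residualize(adj, meta, covariates = cfg$network_covariates)
    cov_vh <- covariance_matrix(res, meta, "VH")
    cov_no <- covariance_matrix(res, meta, "noVH")
    edges <- compare_edges(cov_vh, cov_no)
    hub_vh <- identify_hubs(betweenness_sweep(cov_vh, cfg$densities))
    hub_no <- identify_hubs(betweenness_sweep(cov_no, cfg$densities))
    cseeds <- derive_seeds(seeds[["perm"]], c("comm_vh", "comm_no", "boot"))
    tg_vh <- threshold_graph(cov_vh, cfg$display_density)
    tg_no <- threshold_graph(cov_no, cfg$display_density)
    comm_vh <- detect_communities(tg_vh, seed = cseeds[["comm_vh"]],
                                  restarts = cfg$louvain_restarts)
    comm_no <- detect_communities(tg_no, seed = cseeds[["comm_no"]],
                                  restarts = cfg$louvain_restarts)
    boot_no <- bootstrap_modularity(res, meta, "noVH",
                                    density = cfg$display_density,
                                    reps = min(cfg$n_boot, 200L),
                                    seed = cseeds[["boot"]])
    list(
      n_edges_tested = nrow(edges),
      n_edges_fdr = sum(edges$p_fdr <= cfg$fdr),
      edges_top = utils::head(edges[order(edges$p), ], 20),
      hubs_vh = hub_vh$hubs, hubs_no = hub_no$hubs,
      modularity_vh = comm_vh$Q, modularity_no = comm_no$Q,
      communities_vh = comm_vh$membership, communities_no = comm_no$membership,
      modularity_boot_no = boot_no[c("mean", "sd", "ci")]
    )
  })

  class(report) <- "pipeline_report"
  if (!is.null(cfg$out)) write_report(report, bundle, cfg$out)
  report
}

# Serialize the report and main tables under an output directory.
write_report <- function(report, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$screening$table,
                   file.path(out_dir, "screening.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$difference_map),
                   file.path(out_dir, "difference_map.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Reduce the report to plain JSON-serializable values.
report_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(as.list(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(list(
    seeds = report$seeds,
    harmonisation = report$harmonisation,
    flagged_regions = report$screening$flagged,
    mancova = report$screening$mancova_multivariate,
    receptor = lapply(report$receptor, function(r) {
      list(spin = r$spin,
           fits = lapply(r$fits, function(f)
             f[c("subset_label", "n_regions", "beta_std", "slope", "t", "p",
                 "ci", "outliers_removed")]))
    }),
    pca = report$pca[c("eigenvalues", "n_retained", "variance_pct")],
    network = report$network[c("n_edges_tested", "n_edges_fdr", "hubs_vh",
                               "hubs_no", "modularity_vh", "modularity_no",
                               "modularity_boot_no")],
    warnings = report$warnings
  ))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  site eta2: %.4f -> %.4f\n",
              x$harmonisation$eta2_pre, x$harmonisation$eta2_post))
  cat(sprintf("  flagged regions: %d\n", length(x$screening$flagged)))
  if (length(x$receptor)) {
    for (lab in names(x$receptor)) {
      cat(sprintf("  receptor %s: spin r = %.3f, p = %.4f\n", lab,
                  x$receptor[[lab]]$spin$r_obs,
                  x$receptor[[lab]]$spin$p_spin))
    }
  }
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA: %d dimensions retained\n", x$pca$n_retained))
  }
  cat(sprintf("  network: %d/%d edges FDR-significant; Q(VH) = %.3f, Q(noVH) = %.3f\n",
              x$network$n_edges_fdr, x$network$n_edges_tested,
              x$network$modularity_vh, x$network$modularity_no))
  invisible(x)
}
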
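#' Align a receptor map with a difference map over an atlas
#'
#' Pairs per-region binding potential with the group difference of means
#' over the label intersection of map, difference map, optional subset, and
#' atlas, after removing excluded regions (e.g. cerebellar parcels in
#' reference-region binding models). Label-keyed, so input order never
#' matters.
#'
#' @param map Receptor map data.frame (`region_id`, `bp`).
#' @param diff Difference map data.frame (`region_id`, `diff`).
#' @param atlas Optional atlas restricting the region universe.
#' @param subset Optional character vector of region ids to keep.
#' @param exclude Region ids carrying no usable binding potential.
#' @return A list with aligned `region_id`, `bp`, `diff`, and `dropped`
#'   (labels present somewhere but not in the pairing).
#' @export
align_receptor_map <- function(map, diff, atlas = NULL, subset = NULL,
                               exclude = character()) {
  stopifnot(all(c("region_id", "bp") %in% names(map)),
            all(c("region_id", "diff") %in% names(diff)))
  ids <- intersect(map$region_id, diff$region_id)
  if (!is.null(atlas)) ids <- intersect(ids, atlas$region_id)
  if (!is.null(subset)) ids <- intersect(ids, subset)
  ids <- setdiff(ids, exclude)
  if (length(ids) == 0L) {
    stop("empty region intersection; map regions: ",
         paste(utils::head(map$region_id, 3), collapse = ", "),
         " ... vs difference-map regions: ",
         paste(utils::head(diff$region_id, 3), collapse = ", "),
         call. = FALSE)
  }
  ids <- ids[order(match(ids, map$region_id))]
  dropped <- setdiff(union(map$region_id, diff$region_id), ids)
  list(region_id = ids,
       bp = map$bp[match(ids, map$region_id)],
       diff = diff$diff[match(ids, diff$region_id)],
       dropped = dropped)
}

#' Regression of a group difference map on receptor binding potential
#'
#' Simple OLS of the per-region difference of means on binding potential,
#' reporting the standardized slope (both variables z-scored; equal to the
#' Pearson correlation for a simple regression), Cook's distance influence
#' diagnostics with optional refit excluding points with D > 1, and a seeded
#' percentile bootstrap confidence interval for the unstandardized slope.
#'
#' Both the initial and the post-removal fit are kept; the headline numbers
#' (`beta_std`, `t`, `p`, `ci`) come from the post-removal fit when a refit
#' happened.
#'
#' @param diff,bp Aligned numeric vectors (see [align_receptor_map()]).
#' @param subset_label `"significant"`, `"all"` or `"nonsignificant"` — the
#'   region subset this fit describes; propagated to outputs.
#' @param refit_influential Refit without points with Cook's D > 1
#'   (default TRUE). If every point is influential the refit is refused and
#'   the initial fit returned with a warning.
#' @param n_boot Bootstrap resamples for the slope CI.
#' @param level CI level.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `receptor_assoc`: `beta_std`, `t`, `p`,
#'   `slope`, `ci`, `n_regions`, `outliers_removed`, `subset_label`,
#'   `initial` (pre-removal numbers), and the aligned data.
#' @export
fit_receptor_regression <- function(diff, bp, subset_label = "all",
                                    refit_influential = TRUE,
                                    n_boot = 10000L, level = 0.95,
                                    seed = 1L) {
  stopifnot(length(diff) == length(bp))
  n <- length(diff)
  if (n < 8L) stop("need >= 8 paired regions", call. = FALSE)
  if (stats::sd(bp) == 0) stop("zero-variance predictor", call. = FALSE)
  ids <- names(diff) %||% as.character(seq_len(n))

  ols <- function(y, x) {
    fit <- stats::lm(y ~ x)
    s <- summary(fit)$coefficients
    perfect <- stats::sd(fit$residuals) < 1e-12 * max(stats::sd(y), 1)
    list(fit = fit, slope = unname(stats::coef(fit)[2]),
         beta_std = unname(stats::coef(fit)[2]) * stats::sd(x) / stats::sd(y),
         t = if (perfect) Inf * sign(stats::coef(fit)[2]) else s[2, "t value"],
         p = if (perfect) 0 else s[2, "Pr(>|t|)"])
  }
  fit0 <- ols(diff, bp)
  cook <- stats::cooks.distance(fit0$fit)
  influential <- which(!is.na(cook) & cook > 1)

  keep <- seq_len(n)
  final <- fit0
  removed <- character()
  if (refit_influential && length(influential)) {
    if (length(influential) >= n - 2L) {
      warning("all (or nearly all) points influential; refit refused, ",
              "returning the initial fit")
    } else {
      keep <- setdiff(seq_len(n), influential)
      final <- ols(diff[keep], bp[keep])
      removed <- ids[influential]
    }
  }

  boot_ci <- with_seed(seed, {
    nb <- length(keep)
    idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nb, n_boot)
    xb <- matrix(bp[keep][idx], nb, n_boot)
    yb <- matrix(diff[keep][idx], nb, n_boot)
    mx <- colMeans(xb); my <- colMeans(yb)
    sxx <- colSums(xb^2) - nb * mx^2
    sxy <- colSums(xb * yb) - nb * mx * my
    slopes <- sxy / sxx
    slopes <- slopes[is.finite(slopes)]
    stats::quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE, type = 7)
  })

  out <- list(
    subset_label = subset_label, n_regions = length(keep),
    beta_std = final$beta_std, slope = final$slope,
    t = final$t, p = final$p,
    ci = boot_ci, ci_level = level, n_boot = as.integer(n_boot),
    outliers_removed = removed,
    initial = list(beta_std = fit0$beta_std, slope = fit0$slope,
                   t = fit0$t, p = fit0$p, n_regions = n),
    cooks_distance = stats::setNames(as.numeric(cook), ids),
    data = list(region_id = ids, diff = as.numeric(diff),
                bp = as.numeric(bp)),
    seed = as.integer(seed)
  )
  class(out) <- "receptor_assoc"
  out
}

#' @export
print.receptor_assoc <- function(x, ...) {
  cat(sprintf(
    "Receptor association (%s regions, n = %d): beta_std = %.3f, t = %.2f, p = %.3g\n",
    x$subset_label, x$n_regions, x$beta_std, x$t, x$p))
  cat(sprintf("  %d%% bootstrap CI for the slope: [%.4g, %.4g] (%d resamples)\n",
              round(100 * x$ci_level), x$ci[1], x$ci[2], x$n_boot))
  if (length(x$outliers_removed)) {
    cat("  influential points removed (Cook's D > 1): ",
        paste(x$outliers_removed, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Compare the slopes of two receptor regressions
#'
#' Stacked-model interaction test: the shared outcome is regressed on the
#' standardized predictor, a receptor indicator, and their interaction over
#' the concatenated data of both fits; the interaction t tests whether the
#' standardized slopes differ.
#'
#' @param res_a,res_b `receptor_assoc` objects fitted on the same region
#'   subset and the same outcome (checked; the pre-removal data are used).
#' @return A list with `t`, `df`, `p`, and the two standardized slopes.
#' @export
compare_slopes <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "receptor_assoc"),
            inherits(res_b, "receptor_assoc"))
  if (!identical(res_a$subset_label, res_b$subset_label)) {
    stop("fits are on different region subsets", call. = FALSE)
  }
  if (!isTRUE(all.equal(res_a$data$diff, res_b$data$diff))) {
    stop("fits have different outcomes; slopes are not comparable",
         call. = FALSE)
  }
  y <- c(res_a$data$diff, res_b$data$diff)
  x <- c(as.numeric(scale(res_a$data$bp)), as.numeric(scale(res_b$data$bp)))
  g <- factor(rep(c("A", "B"), times = c(length(res_a$data$diff),
                                         length(res_b$data$diff))))
  fit <- stats::lm(y ~ x * g)
  s <- summary(fit)$coefficients
  row <- grep("^x:g", rownames(s))
  list(t = s[row, "t value"], df = fit$df.residual,
       p = s[row, "Pr(>|t|)"],
       slope_std_a = res_a$beta_std, slope_std_b = res_b$beta_std)
}
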
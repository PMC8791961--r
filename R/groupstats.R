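#' Region screening by covariate-adjusted ANOVA with BH-FDR
#'
#' Per-region ANCOVA of the morphometric value on group, adjusting for the
#' declared covariates, with Benjamini-Hochberg step-up correction over all
#' regions of the measure (the FDR family is one measure's region set, never
#' pooled across measures). Regions flagged at `q` feed the MANCOVA and PCA
#' stages.
#'
#' @param values Subjects x regions matrix.
#' @param meta Metadata with `group` (levels VH / noVH) and covariates.
#' @param covariates Covariate columns; default age, gender, TIV.
#' @param q FDR level for flagging.
#' @return A data.frame with per-region `F`, `df1`, `df2`, `p`, `p_fdr`,
#'   `partial_eta2`, `direction` (sign of the adjusted VH - noVH difference)
#'   and `flagged`. Constant regions get `p = NaN` and are excluded from the
#'   FDR family (with a message).
#' @export
screen_regions_anova <- function(values, meta,
                                 covariates = c("age", "gender", "tiv"),
                                 q = 0.05) {
  assert_morph_table(values)
  meta <- align_meta(values, meta)
  grp <- check_groups(meta)
  covariates <- intersect(covariates, names(meta))
  Xc <- covariate_design(meta, covariates)
  X_red <- cbind(`(Intercept)` = 1, Xc)
  X_full <- cbind(X_red, groupVH = as.numeric(grp == "VH"))
  check_full_rank(X_full, "screening design matrix")

  N <- nrow(values)
  fit_red <- stats::lm.fit(X_red, values)
  fit_full <- stats::lm.fit(X_full, values)
  rss_red <- colSums(fit_red$residuals^2)
  rss_full <- colSums(fit_full$residuals^2)
  df1 <- 1L
  df2 <- N - ncol(X_full)
  Fv <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  const <- apply(values, 2, function(v) stats::var(v) == 0) | rss_red <= 0
  if (any(const)) {
    message("constant region(s) excluded from the FDR family: ",
            paste(colnames(values)[const], collapse = ", "))
    Fv[const] <- NaN
  }
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p_fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(
    region_id = colnames(values),
    F = Fv, df1 = df1, df2 = df2, p = p, p_fdr = p_fdr,
    partial_eta2 = ifelse(const, NA_real_, 1 - rss_full / rss_red),
    direction = sign(fit_full$coefficients["groupVH", ]),
    flagged = !is.na(p_fdr) & p_fdr <= q,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "q") <- q
  out
}

check_groups <- function(meta) {
  grp <- factor(meta$group, levels = c("noVH", "VH"))
  if (anyNA(grp)) {
    stop("group must be 'VH' or 'noVH' for every subject", call. = FALSE)
  }
  if (nlevels(droplevels(grp)) < 2L) {
    stop("both groups (VH and noVH) must be present", call. = FALSE)
  }
  grp
}

#' Covariate-adjusted multivariate group comparison (MANCOVA)
#'
#' Multivariate linear model of the selected regions on covariates plus
#' group (plus declared interaction terms), with a multivariate test per
#' model term (Pillai's trace by default; Wilks via `statistic`), per-region
#' between-subject F tests with partial eta squared, and Bonferroni-corrected
#' pairwise group contrasts (family = number of regions entered).
#'
#' Terms are tested sequentially with group entered last, so the group test
#' is adjusted for every covariate.
#'
#' @param values Subjects x regions matrix.
#' @param meta Metadata.
#' @param regions Region ids entered as dependent variables (e.g. the
#'   screening survivors).
#' @param covariates Covariate columns.
#' @param interactions Character vector of interaction terms between
#'   covariates, e.g. `c("age:led", "onset:updrs3")`.
#' @param statistic `"Pillai"` (default) or `"Wilks"`.
#' @return A list of class `mancova_result` with elements `multivariate`
#'   (per-term statistic, approximate F, dfs, p), `per_region` (F, p,
#'   partial eta squared for the group term), and `pairwise`
#'   (adjusted VH - noVH difference, t, raw and Bonferroni p per region).
#' @export
fit_mancova <- function(values, meta, regions,
                        covariates = c("age", "gender", "tiv"),
                        interactions = character(),
                        statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  assert_morph_table(values)
  meta <- align_meta(values, meta)
  grp <- check_groups(meta)
  if (length(regions) == 0L) stop("`regions` must be nonempty", call. = FALSE)
  miss <- setdiff(regions, colnames(values))
  if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  covariates <- intersect(covariates, names(meta))
  m <- length(regions)
  N <- nrow(values)
  if (N <= m + length(covariates) + 2L) {
    stop("too few subjects for a MANCOVA on ", m,
         " regions; enter fewer regions", call. = FALSE)
  }

  dat <- meta[, covariates, drop = FALSE]
  chr <- vapply(dat, is.character, logical(1))
  dat[chr] <- lapply(dat[chr], factor)
  dat$group <- grp
  Y <- values[, regions, drop = FALSE]
  rhs <- paste(c(covariates, interactions, "group"), collapse = " + ")
  if (rhs == "group") rhs <- "group"
  fml <- stats::as.formula(paste("Y ~", rhs))
  mlm <- stats::lm(fml, data = dat)

  res_rank <- qr(stats::residuals(mlm))$rank
  if (res_rank < m) {
    stop("within-groups covariance of the dependent regions is singular; ",
         "enter fewer regions", call. = FALSE)
  }
  if (m == 1L) {
    # one dependent region: the multivariate test degenerates to ANOVA
    an1 <- stats::anova(mlm)
    keep <- rownames(an1) != "Residuals"
    mv_df <- data.frame(
      term = rownames(an1)[keep],
      statistic = NA_real_,
      approx_F = an1[keep, "F value"],
      df_num = an1[keep, "Df"], df_den = an1["Residuals", "Df"],
      p = an1[keep, "Pr(>F)"],
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    mv <- tryCatch(stats::anova(mlm, test = statistic),
                   error = function(e) stop(
                     "multivariate test failed (", conditionMessage(e),
                     "); consider entering fewer regions", call. = FALSE))
    mv_df <- data.frame(
      term = rownames(mv),
      statistic = mv[[statistic]],
      approx_F = mv[["approx F"]],
      df_num = mv[["num Df"]], df_den = mv[["den Df"]],
      p = mv[["Pr(>F)"]],
      row.names = NULL, stringsAsFactors = FALSE
    )
    mv_df <- mv_df[!mv_df$term %in% c("(Intercept)", "Residuals"), ,
                   drop = FALSE]
  }

  # per-region sequential ANOVA, group last
  per_region <- do.call(rbind, lapply(regions, function(r) {
    y <- values[, r]
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
    an <- stats::anova(fit)
    ss_grp <- an["group", "Sum Sq"]
    ss_res <- an["Residuals", "Sum Sq"]
    data.frame(
      region_id = r,
      F = an["group", "F value"],
      df1 = an["group", "Df"], df2 = an["Residuals", "Df"],
      p = an["group", "Pr(>F)"],
      partial_eta2 = ss_grp / (ss_grp + ss_res),
      estimate = stats::coef(fit)[["groupVH"]],
      t = summary(fit)$coefficients["groupVH", "t value"],
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_region) <- NULL
  pairwise <- data.frame(
    region_id = per_region$region_id,
    diff_adj = per_region$estimate,
    t = per_region$t,
    p = per_region$p,
    p_bonferroni = pmin(1, m * per_region$p),
    stringsAsFactors = FALSE
  )
  out <- list(multivariate = mv_df,
              per_region = per_region[, c("region_id", "F", "df1", "df2",
                                          "p", "partial_eta2")],
              pairwise = pairwise,
              statistic = statistic, regions = regions,
              covariates = covariates, interactions = interactions)
  class(out) <- "mancova_result"
  out
}

#' @export
print.mancova_result <- function(x, ...) {
  cat(sprintf("MANCOVA (%s) on %d regions, covariates: %s\n",
              x$statistic, length(x$regions),
              paste(x$covariates, collapse = ", ")))
  print(x$multivariate, digits = 4)
  invisible(x)
}

#' Unadjusted group difference-of-means map
#'
#' Per-region difference of group means, VH minus noVH (so planted thinning
#' in VH gives negative values for thickness), with pooled-variance standard
#' errors.
#'
#' @param values Subjects x regions matrix.
#' @param meta Metadata with `group`.
#' @return A data.frame (`region_id`, `diff`, `se`) of class
#'   `difference_map`.
#' @export
compute_difference_map <- function(values, meta) {
  assert_morph_table(values)
  meta <- align_meta(values, meta)
  grp <- check_groups(meta)
  n1 <- sum(grp == "VH"); n2 <- sum(grp == "noVH")
  if (n1 == 0L || n2 == 0L) stop("a group is empty", call. = FALSE)
  m_vh <- colMeans(values[grp == "VH", , drop = FALSE])
  m_no <- colMeans(values[grp == "noVH", , drop = FALSE])
  v_vh <- apply(values[grp == "VH", , drop = FALSE], 2, stats::var)
  v_no <- apply(values[grp == "noVH", , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v_vh + (n2 - 1) * v_no) / (n1 + n2 - 2)
  out <- data.frame(
    region_id = colnames(values),
    diff = m_vh - m_no,
    se = sqrt(sp2 * (1 / n1 + 1 / n2)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("difference_map", "data.frame")
  out
}

#' Tukey 1.5 IQR outlier flags
#'
#' Flags values below Q1 - 1.5 IQR or above Q3 + 1.5 IQR. Quartiles use
#' linear interpolation of order statistics (R quantile type 7); the
#' convention only matters in tiny samples and is fixed here for
#' reproducibility.
#'
#' @param values Numeric vector with >= 4 finite values.
#' @return Sorted integer indices of the flagged values.
#' @export
flag_outliers_tukey <- function(values) {
  if (sum(is.finite(values)) < 4L) {
    stop("need at least 4 finite values", call. = FALSE)
  }
  qs <- stats::quantile(values[is.finite(values)], c(0.25, 0.75), type = 7,
                        names = FALSE)
  iqr <- qs[2] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[2] + 1.5 * iqr
  which(is.finite(values) & (values < lo | values > hi))
}

#' Mean imputation of missing scores
#'
#' Replaces missing entries by the mean of the observed entries: the pooled
#' sample mean by default, or group-wise means when `groups` is supplied.
#' Observed entries are never touched.
#'
#' @param values Numeric vector with `NA` for missing.
#' @param groups Optional grouping vector (same length); per-group means.
#' @return The completed vector.
#' @export
impute_group_mean <- function(values, groups = NULL) {
  miss <- is.na(values)
  if (!any(miss)) return(values)
  if (is.null(groups)) {
    if (all(miss)) stop("no observed values to impute from", call. = FALSE)
    values[miss] <- mean(values[!miss])
    return(values)
  }
  stopifnot(length(groups) == length(values))
  for (g in unique(groups[miss])) {
    sel <- groups == g
    obs <- values[sel & !miss]
    if (length(obs) == 0L) {
      stop("group '", g, "' has a missing entry but no observed values",
           call. = FALSE)
    }
    values[sel & miss] <- mean(obs)
  }
  values
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after OLS on the
#' covariates, with a t-based two-sided p-value on n - 2 - k degrees of
#' freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional vector, matrix or data.frame of controls.
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    C <- matrix(numeric(0), n, 0)
  } else {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
  }
  k <- ncol(C)
  if (n <= k + 3L) stop("need n > n_covariates + 3", call. = FALSE)
  X <- cbind(1, C)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant residuals: partial correlation undefined", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       df = df, n = n)
}

#' Random-effects meta-analysis of per-study mean differences
#'
#' DerSimonian-Laird random-effects pooling with inverse-variance weights
#' and a Wald confidence interval, via `metafor::rma.uni(method = "DL")`.
#' A single study degenerates to that study's estimate with tau^2 = 0 and a
#' warning.
#'
#' @param md Per-study mean differences.
#' @param v Per-study variances (> 0).
#' @param level Confidence level.
#' @return A list with `estimate`, `se`, `ci_lb`, `ci_ub`, `tau2`, `Q`, `k`.
#' @export
meta_analyze <- function(md, v, level = 0.95) {
  stopifnot(length(md) == length(v))
  if (any(v <= 0)) stop("study variances must be positive", call. = FALSE)
  if (length(md) < 2L) {
    warning("single study: returning its estimate with tau^2 = 0")
    se <- sqrt(v)
    zc <- stats::qnorm(1 - (1 - level) / 2)
    return(list(estimate = md, se = se, ci_lb = md - zc * se,
                ci_ub = md + zc * se, tau2 = 0, Q = 0, k = 1L))
  }
  fit <- metafor::rma.uni(yi = md, vi = v, method = "DL", level = level * 100)
  list(estimate = as.numeric(fit$beta), se = fit$se,
       ci_lb = fit$ci.lb, ci_ub = fit$ci.ub,
       tau2 = fit$tau2, Q = fit$QE, k = fit$k)
}

#' Leave-one-study-out sensitivity analysis
#'
#' Reruns the screening (and a MANCOVA on each run's survivors) with each
#' site held out, reporting per-run flagged-region sets and their Jaccard
#' overlap with the full-sample flags. Runs leaving fewer than 2 subjects in
#' either group are skipped with a warning.
#'
#' @param values,meta Table and metadata.
#' @param covariates Covariates for both stages.
#' @param q FDR level.
#' @return A list with `full_flags` and per-held-out-site entries
#'   (`flagged`, `jaccard`, `mancova`).
#' @export
leave_one_study_out <- function(values, meta,
                                covariates = c("age", "gender", "tiv"),
                                q = 0.05) {
  meta <- align_meta(values, meta)
  sites <- unique(meta$site)
  if (length(sites) < 3L) stop("need >= 3 studies", call. = FALSE)
  full <- screen_regions_anova(values, meta, covariates, q)
  full_flags <- full$region_id[full$flagged]
  runs <- lapply(sites, function(s) {
    keep <- meta$site != s
    sub_meta <- meta[keep, , drop = FALSE]
    if (min(table(factor(sub_meta$group, c("noVH", "VH")))) < 2L) {
      warning("holding out ", s, " leaves < 2 subjects in a group; skipped")
      return(NULL)
    }
    scr <- screen_regions_anova(values[keep, , drop = FALSE], sub_meta,
                                covariates, q)
    flags <- scr$region_id[scr$flagged]
    jac <- if (length(union(flags, full_flags)) == 0) 1 else
      length(intersect(flags, full_flags)) / length(union(flags, full_flags))
    manc <- if (length(flags)) {
      tryCatch(fit_mancova(values[keep, , drop = FALSE], sub_meta, flags,
                           covariates),
               error = function(e) NULL)
    } else NULL
    list(held_out = s, flagged = flags, jaccard = jac, mancova = manc)
  })
  names(runs) <- sites
  list(full_flags = full_flags, runs = runs[!vapply(runs, is.null,
                                                    logical(1))])
}

#' Group comparisons of demographic and clinical variables
#'
#' One-way ANOVA per continuous variable, chi-square (uncorrected by
#' default) per categorical variable, and a Brown-Forsythe (median-centred)
#' Levene test of variance homogeneity per continuous variable.
#'
#' @param meta Metadata with `group`.
#' @param continuous,categorical Variable names; defaults pick the standard
#'   demographic columns present.
#' @param chisq_correct Yates continuity correction for the chi-square.
#' @param levene_center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @return A data.frame with one row per variable: test type, statistic,
#'   df, p, and Levene p for continuous variables. Chi-square is refused
#'   (NA, with a message) when any expected cell count is 0.
#' @export
compare_demographics <- function(meta,
                                 continuous = intersect(
                                   c("age", "tiv", "led", "mmse", "updrs3",
                                     "onset"), names(meta)),
                                 categorical = intersect("gender",
                                                         names(meta)),
                                 chisq_correct = FALSE,
                                 levene_center = c("median", "mean")) {
  levene_center <- match.arg(levene_center)
  grp <- check_groups(meta)
  center_fun <- if (levene_center == "median") stats::median else mean
  rows <- list()
  for (v in continuous) {
    x <- meta[[v]]
    ok <- !is.na(x)
    an <- stats::anova(stats::lm(x[ok] ~ grp[ok]))
    lev <- car::leveneTest(x[ok] ~ grp[ok], center = center_fun)
    rows[[v]] <- data.frame(
      variable = v, type = "anova",
      statistic = an[1, "F value"], df = an[1, "Df"],
      p = an[1, "Pr(>F)"], levene_p = lev[1, "Pr(>F)"],
      stringsAsFactors = FALSE
    )
  }
  for (v in categorical) {
    tab <- table(meta[[v]], grp)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts == 0)) {
      message("chi-square refused for '", v, "': expected cell count 0")
      rows[[v]] <- data.frame(variable = v, type = "chisq",
                              statistic = NA_real_, df = NA_real_,
                              p = NA_real_, levene_p = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    ch <- suppressWarnings(stats::chisq.test(tab, correct = chisq_correct))
    rows[[v]] <- data.frame(variable = v, type = "chisq",
                            statistic = unname(ch$statistic),
                            df = unname(ch$parameter), p = ch$p.value,
                            levene_p = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
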
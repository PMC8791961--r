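#' Fit a parametric empirical-Bayes location-scale harmonisation model
#'
#' Removes additive and multiplicative site/scanner effects from a
#' subjects x regions morphometric table while preserving declared biological
#' covariates (ComBat-type harmonisation). The model for subject j at site s,
#' region r is
#' \deqn{y_{jsr} = \alpha_r + X_j \beta_r + \gamma_{sr} +
#'   \delta_{sr} \varepsilon_{jsr}}
#' Per-region location/scale site effects are estimated in standardized
#' units, then shrunk across regions by parametric empirical Bayes: a normal
#' prior on locations and an inverse-gamma prior on squared scales, with
#' hyperparameters by method of moments and posterior means iterated to
#' convergence.
#'
#' @param values Subjects x regions matrix (one morphometric kind; harmonise
#'   thickness, area and volume separately).
#' @param meta Metadata with `subject_id`, `site`, and the covariate columns.
#' @param biological_covariates Metadata columns whose variance must survive
#'   harmonisation. Default protects the group contrast plus age, gender and
#'   TIV.
#' @param eb Apply empirical-Bayes shrinkage (`TRUE`, the default); `FALSE`
#'   uses the raw per-site estimates (no pooling across regions).
#' @param tol,max_iter Convergence tolerance (max absolute change in any
#'   posterior mean) and iteration cap for the EB updates.
#' @return An object of class `combat_fit` with elements `alpha` (grand mean
#'   per region), `beta` (covariate coefficients per region), `sigma`
#'   (pooled residual SD), `gamma_star` / `delta_star` (shrunken additive /
#'   multiplicative site effects in standardized units), the unshrunk
#'   estimates, per-site hyperparameters, and convergence information.
#' @seealso [apply_combat()] to adjust data, [site_effect_report()] for
#'   before/after audits.
#' @examples
#' atl <- generate_atlas(8, seed = 1)
#' tr <- cohort_truth(atl, n_sites = 2, seed = 2)
#' coh <- generate_cohort(atl, tr, 20, seed = 3)
#' fit <- fit_combat(coh$values, coh$meta)
#' adj <- apply_combat(fit, coh$values, coh$meta)
#' @export
fit_combat <- function(values, meta,
                       biological_covariates = c("group", "age", "gender",
                                                 "tiv"),
                       eb = TRUE, tol = 1e-6, max_iter = 200L) {
  assert_morph_table(values)
  meta <- align_meta(values, meta)
  site <- factor(meta$site)
  if (nlevels(site) < 2L) {
    stop("harmonisation needs >= 2 sites (nothing to harmonise)",
         call. = FALSE)
  }
  n_s <- table(site)
  if (any(n_s < 3L)) {
    stop("every site needs >= 3 subjects; too small: ",
         paste(names(n_s)[n_s < 3L], collapse = ", "), call. = FALSE)
  }
  biological_covariates <- intersect(biological_covariates, names(meta))
  Xc <- covariate_design(meta, biological_covariates)
  Xs <- stats::model.matrix(~ site - 1)
  colnames(Xs) <- levels(site)
  X <- cbind(Xs, Xc)
  check_full_rank(X, "harmonisation design matrix")

  N <- nrow(values); R <- ncol(values); S <- nlevels(site)
  fit <- stats::lm.fit(X, values)
  B <- fit$coefficients
  gamma_raw <- B[seq_len(S), , drop = FALSE]          # per-site intercepts
  beta <- B[-seq_len(S), , drop = FALSE]
  w <- as.numeric(n_s) / N
  alpha <- as.numeric(crossprod(w, gamma_raw))        # weighted grand mean
  names(alpha) <- colnames(values)
  sigma <- sqrt(colMeans(fit$residuals^2))
  if (any(sigma <= 0)) {
    stop("constant region(s) after model fit: ",
         paste(colnames(values)[sigma <= 0], collapse = ", "), call. = FALSE)
  }

  bio_fit <- matrix(alpha, N, R, byrow = TRUE)
  if (ncol(Xc) > 0) bio_fit <- bio_fit + Xc %*% beta
  Z <- (values - bio_fit) / matrix(sigma, N, R, byrow = TRUE)

  site_idx <- split(seq_len(N), site)
  gamma_hat <- t(vapply(site_idx, function(ix) colMeans(Z[ix, , drop = FALSE]),
                        numeric(R)))
  delta2_hat <- t(vapply(site_idx, function(ix) {
    apply(Z[ix, , drop = FALSE], 2, stats::var)
  }, numeric(R)))
  dimnames(gamma_hat) <- dimnames(delta2_hat) <- list(levels(site),
                                                      colnames(values))

  hyper <- data.frame(site = levels(site), gamma_bar = NA_real_,
                      tau2 = NA_real_, a_prior = NA_real_, b_prior = NA_real_)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  n_iter <- 0L; converged <- TRUE
  if (eb) {
    if (R < 4L) {
      warning("fewer than 4 regions: EB moment estimates are unstable; ",
              "using raw site effects (no shrinkage)")
      eb <- FALSE
    }
  }
  if (eb) {
    for (s in seq_len(S)) {
      g <- gamma_hat[s, ]; d2 <- delta2_hat[s, ]
      gbar <- mean(g); tau2 <- stats::var(g)
      m <- mean(d2); v <- stats::var(d2)
      a <- (2 * v + m^2) / v
      b <- (m * v + m^3) / v
      shrink_scale <- is.finite(a) && is.finite(b) && v > 0
      hyper[s, 2:5] <- c(gbar, tau2, a, b)
      ns <- as.numeric(n_s[s])
      zs <- Z[site_idx[[s]], , drop = FALSE]
      g_st <- g; d2_st <- d2
      change <- Inf
      for (it in seq_len(max_iter)) {
        g_new <- (ns * tau2 * g + d2_st * gbar) / (ns * tau2 + d2_st)
        d2_new <- if (shrink_scale) {
          ss <- colSums((zs - matrix(g_new, ns, R, byrow = TRUE))^2)
          (b + 0.5 * ss) / (ns / 2 + a - 1)
        } else d2
        change <- max(abs(g_new - g_st), abs(d2_new - d2_st))
        g_st <- g_new; d2_st <- d2_new
        if (change < tol) break
      }
      n_iter <- max(n_iter, it)
      if (change >= tol) {
        converged <- FALSE
        warning(sprintf(
          "EB updates for site %s did not converge in %d iterations",
          levels(site)[s], max_iter))
      }
      gamma_star[s, ] <- g_st
      delta2_star[s, ] <- d2_st
    }
  }
  if (any(delta2_star <= 0)) {
    stop("non-positive shrunken scale estimate; data degenerate", call. = FALSE)
  }

  cov_levels <- lapply(meta[intersect(biological_covariates, names(meta))],
                       function(x) if (is.character(x) || is.factor(x))
                         levels(factor(x)) else NULL)
  out <- list(
    alpha = alpha, beta = beta, sigma = sigma,
    gamma_star = gamma_star, delta_star = sqrt(delta2_star),
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    hyperparameters = hyper, eb = eb,
    n_iter = n_iter, converged = converged,
    sites = levels(site), n_per_site = as.integer(n_s),
    covariates = biological_covariates, cov_levels = cov_levels,
    cov_colnames = colnames(Xc), regions = colnames(values),
    measure = attr(values, "measure") %||% "thickness"
  )
  class(out) <- "combat_fit"
  out
}

# Rebuild the biological-covariate design for new metadata with the factor
# codings used at fit time.
rebuild_cov_design <- function(fit, meta) {
  df <- meta
  for (nm in names(fit$cov_levels)) {
    lv <- fit$cov_levels[[nm]]
    if (!is.null(lv)) df[[nm]] <- factor(df[[nm]], levels = lv)
  }
  Xc <- covariate_design(df, fit$covariates)
  if (!identical(colnames(Xc), fit$cov_colnames)) {
    stop("covariate design at apply time does not match the fit",
         call. = FALSE)
  }
  Xc
}

#' Apply a fitted harmonisation to a morphometric table
#'
#' Standardizes each value with the fitted biological model, removes the
#' shrunken site location effect, divides by the shrunken site scale effect,
#' and restores the biological fit:
#' \deqn{y^{adj} = \frac{\hat\sigma_r}{\delta^*_{sr}}
#'   (z - \gamma^*_{sr}) + \hat\alpha_r + X \hat\beta_r}
#'
#' @param fit A [fit_combat()] object.
#' @param values,meta Table and metadata to adjust; all sites must have been
#'   seen at fit time (there is no out-of-sample site adjustment).
#' @return The adjusted matrix, same shape and dimnames.
#' @export
apply_combat <- function(fit, values, meta) {
  stopifnot(inherits(fit, "combat_fit"))
  assert_morph_table(values)
  if (!identical(colnames(values), fit$regions)) {
    stop("table regions do not match the fit", call. = FALSE)
  }
  meta <- align_meta(values, meta)
  unseen <- setdiff(unique(meta$site), fit$sites)
  if (length(unseen)) {
    stop("site(s) not present in the fit: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  N <- nrow(values); R <- ncol(values)
  Xc <- rebuild_cov_design(fit, meta)
  bio_fit <- matrix(fit$alpha, N, R, byrow = TRUE)
  if (ncol(Xc) > 0) bio_fit <- bio_fit + Xc %*% fit$beta
  Z <- (values - bio_fit) / matrix(fit$sigma, N, R, byrow = TRUE)
  s_idx <- match(meta$site, fit$sites)
  Zadj <- (Z - fit$gamma_star[s_idx, , drop = FALSE]) /
    fit$delta_star[s_idx, , drop = FALSE]
  out <- Zadj * matrix(fit$sigma, N, R, byrow = TRUE) + bio_fit
  dimnames(out) <- dimnames(values)
  attr(out, "measure") <- attr(values, "measure")
  out
}

#' Per-region site-effect ANOVA report
#'
#' One-way ANOVA of each region on the site factor (optionally after
#' residualizing on covariates), reporting F, p and the site-factor eta
#' squared. Run before and after harmonisation to audit how much
#' between-site variance was removed.
#'
#' @param values Subjects x regions matrix.
#' @param meta Metadata with `site`.
#' @param covariates Optional covariate columns to residualize on first.
#' @return A data.frame with `region_id`, `F`, `df1`, `df2`, `p`, `eta2`.
#' @export
site_effect_report <- function(values, meta, covariates = NULL) {
  assert_morph_table(values)
  meta <- align_meta(values, meta)
  site <- factor(meta$site)
  if (nlevels(site) < 2L) stop("need >= 2 sites", call. = FALSE)
  Y <- values
  if (!is.null(covariates) && length(covariates)) {
    Xc <- cbind(1, covariate_design(meta, covariates))
    Y <- stats::lm.fit(Xc, Y)$residuals
  }
  N <- nrow(Y); S <- nlevels(site)
  gm <- colMeans(Y)
  Yc <- sweep(Y, 2, gm)
  site_sums <- rowsum(Yc, site)
  n_s <- as.numeric(table(site))
  ssb <- colSums(site_sums^2 / n_s)
  sst <- colSums(Yc^2)
  ssw <- sst - ssb
  df1 <- S - 1L; df2 <- N - S
  Fv <- (ssb / df1) / (ssw / df2)
  data.frame(
    region_id = colnames(values),
    F = Fv, df1 = df1, df2 = df2,
    p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
    eta2 = ssb / sst,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.combat_fit <- function(x, ...) {
  cat(sprintf(
    "Empirical-Bayes harmonisation fit: %d regions, %d sites (%s)\n",
    length(x$regions), length(x$sites), paste(x$sites, collapse = ", ")))
  cat(sprintf("  covariates protected: %s\n",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  cat(sprintf("  EB shrinkage: %s; iterations: %d; converged: %s\n",
              x$eb, x$n_iter, x$converged))
  invisible(x)
}
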
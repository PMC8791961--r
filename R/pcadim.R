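#' Correlation-matrix principal component analysis of region values
#'
#' PCA of the region-by-region Pearson correlation matrix (variables
#' standardized), as used to reduce a set of group-different regions to a
#' few latent dimensions. Reports eigenvalues, variance fractions, variable
#' loadings (eigenvector times square-root eigenvalue, i.e. the correlation
#' of each region with each component), per-region contributions (% of each
#' component), and cos-squared quality of representation.
#'
#' Sign convention: within each component the entry with the largest
#' absolute loading is made positive, so loadings are reproducible across
#' implementations.
#'
#' @param values Subjects x regions matrix restricted to the regions of
#'   interest (>= 2 regions, >= 3 subjects, no constant region).
#' @return An object of class `pca_result`: `eigenvalues`,
#'   `variance_fraction`, `loadings`, `contributions`, `cos2`, `scores`,
#'   `n_regions`, `n_subjects`.
#' @export
run_pca <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need >= 2 regions", call. = FALSE)
  if (nrow(values) < 3L) stop("need >= 3 subjects", call. = FALSE)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant region(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(values)
  Cmat <- stats::cor(values)
  eig <- eigen(Cmat, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  V <- eig$vectors
  # fix signs: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  loadings <- V %*% diag(sqrt(ev), nrow = length(ev))
  dimnames(loadings) <- list(colnames(values),
                             paste0("Dim", seq_along(ev)))
  contributions <- 100 * V^2
  dimnames(contributions) <- dimnames(loadings)
  cos2 <- loadings^2
  scores <- Z %*% V
  colnames(scores) <- colnames(loadings)
  out <- list(
    eigenvalues = ev,
    variance_fraction = ev / sum(ev),
    loadings = loadings,
    contributions = contributions,
    cos2 = cos2,
    scores = scores,
    n_regions = ncol(values),
    n_subjects = nrow(values)
  )
  class(out) <- "pca_result"
  out
}

#' Retain components and rank their driving regions
#'
#' Applies the Kaiser rule (eigenvalue > 1 in correlation-matrix PCA) by
#' default, or keeps a fixed number of components, and for each retained
#' dimension ranks regions by contribution and by cos-squared. Also emits
#' the scree data for reporting.
#'
#' @param res A [run_pca()] result.
#' @param criterion `"kaiser"` or `"fixed"`.
#' @param n_components Number kept when `criterion = "fixed"`.
#' @param n_top How many top regions to list per dimension.
#' @return A list with `n_retained`, `eigenvalues`, per-dimension
#'   `top_contributors` and `top_cos2` (region id + value), and `scree`
#'   (component, eigenvalue, variance percentage).
#' @export
select_components <- function(res, criterion = c("kaiser", "fixed"),
                              n_components = 2L, n_top = 5L) {
  stopifnot(inherits(res, "pca_result"))
  criterion <- match.arg(criterion)
  n_ret <- switch(criterion,
                  kaiser = sum(res$eigenvalues > 1),
                  fixed = min(n_components, length(res$eigenvalues)))
  n_ret <- max(n_ret, 1L)
  dims <- seq_len(n_ret)
  top <- function(M, k) {
    o <- order(M[, k], decreasing = TRUE)[seq_len(min(n_top, nrow(M)))]
    data.frame(region_id = rownames(M)[o], value = M[o, k],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(
    n_retained = n_ret,
    eigenvalues = res$eigenvalues[dims],
    top_contributors = lapply(dims, function(k) top(res$contributions, k)),
    top_cos2 = lapply(dims, function(k) top(res$cos2, k)),
    scree = data.frame(component = seq_along(res$eigenvalues),
                       eigenvalue = res$eigenvalues,
                       variance_pct = 100 * res$variance_fraction)
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d regions, %d subjects\n",
              x$n_regions, x$n_subjects))
  cat("  eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 6)), collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

# Tucker congruence coefficient between two loading vectors (absolute value:
# component sign is a convention, not substance).
tucker_congruence <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}
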
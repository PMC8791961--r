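# Pairwise angular distance (radians) between unit vectors in the rows of a
# and b.
angular_dist <- function(a, b = a) {
  d <- tcrossprod(a, b)
  acos(pmax(pmin(d, 1), -1))
}

atlas_coords <- function(atlas) {
  as.matrix(atlas[, c("x", "y", "z")])
}

# Gaussian-kernel mixing matrix over parcel centroids: K_ij =
# exp(-theta_ij^2 / (2 l^2)) with l the angular scale in radians. A draw
# K %*% z of white noise z is a spatially smooth field; l -> 0 recovers
# white noise.
smoothing_kernel <- function(atlas, smoothness_deg) {
  th <- angular_dist(atlas_coords(atlas))
  l <- smoothness_deg * pi / 180
  if (l <= 0) return(diag(nrow(th)))
  exp(-th^2 / (2 * l^2))
}

smooth_field <- function(K, n, standardize = TRUE) {
  z <- matrix(stats::rnorm(nrow(K) * n), nrow(K), n)
  f <- K %*% z
  if (standardize) f <- scale(f)
  f
}

#' Generate independent smooth null maps on an atlas
#'
#' Draws `n_maps` independent spatially autocorrelated fields over the parcel
#' centroids (Gaussian-kernel mixing of white noise at the given angular
#' scale). These are the null inputs for spin-test calibration experiments:
#' smooth but statistically unrelated maps, mimicking the spatial
#' autocorrelation that makes naive parametric correlation tests
#' anti-conservative on brain maps.
#'
#' @param atlas Atlas providing centroids.
#' @param smoothness Angular scale in degrees; 0 gives white noise.
#' @param n_maps Number of maps (>= 1).
#' @param seed Integer seed.
#' @return A regions x `n_maps` matrix; each column is one map (zero mean,
#'   unit SD), rownames are region ids.
#' @export
generate_smooth_null_maps <- function(atlas, smoothness = 20, n_maps, seed) {
  validate_atlas(atlas, symmetric = FALSE)
  n_maps <- assert_count(n_maps, "n_maps", min = 1L)
  K <- smoothing_kernel(atlas, smoothness)
  maps <- with_seed(seed, smooth_field(K, n_maps))
  dimnames(maps) <- list(atlas$region_id, paste0("map", seq_len(n_maps)))
  maps[, , drop = FALSE]
}

#' Generate a synthetic receptor binding-potential map
#'
#' Produces a nonnegative, spatially smooth per-region "binding potential"
#' field. When a target difference map and correlation `rho` are supplied,
#' the smooth noise is first orthogonalised against the target and then
#' blended so that the sample Pearson correlation with the target equals
#' `rho` exactly (an affine rescale to nonnegativity preserves it).
#'
#' @param atlas Atlas providing centroids.
#' @param smoothness Angular scale in degrees of the spatial autocorrelation.
#' @param target Optional named numeric difference map over the atlas regions.
#' @param rho Target sample correlation with `target` (|rho| <= 1).
#' @param seed Integer seed.
#' @param receptor_label Label carried on the output (e.g. "5HT2A").
#' @return A data.frame with columns `region_id`, `bp`, and attribute
#'   `receptor_label`.
#' @export
generate_receptor_map <- function(atlas, smoothness = 20, target = NULL,
                                  rho = NULL, seed = 1L,
                                  receptor_label = "synthetic") {
  validate_atlas(atlas, symmetric = FALSE)
  R <- nrow(atlas)
  K <- smoothing_kernel(atlas, smoothness)
  f <- as.numeric(with_seed(seed, smooth_field(K, 1)))
  if (!is.null(target)) {
    if (is.null(rho) || abs(rho) > 1) {
      stop("with a target map, `rho` must be given with |rho| <= 1",
           call. = FALSE)
    }
    t_vec <- target[atlas$region_id]
    if (anyNA(t_vec)) stop("target map does not cover all atlas regions",
                           call. = FALSE)
    if (stats::sd(t_vec) == 0) {
      stop("degenerate target map: zero variance", call. = FALSE)
    }
    t_std <- as.numeric(scale(t_vec))
    # orthogonalise the smooth noise against the target in-sample, then blend
    u <- f - t_std * sum(f * t_std) / sum(t_std^2)
    if (stats::sd(u) == 0) u <- stats::rnorm(R)  # degenerate only if f == t
    u_std <- as.numeric(scale(u))
    f <- rho * t_std + sqrt(1 - rho^2) * u_std
  }
  # affine rescale to a nonnegative, plausibly scaled BP field
  bp <- f - min(f) + 0.1
  out <- data.frame(region_id = atlas$region_id, bp = bp,
                    stringsAsFactors = FALSE)
  attr(out, "receptor_label") <- receptor_label
  out
}

# Moran-type spatial autocorrelation statistic: mean correlation-weighted
# covariance of a map with its centroid-adjacent values. Used in tests to
# check the smoothness knob.
moran_neighbour_stat <- function(atlas, map, k = 3L) {
  th <- angular_dist(atlas_coords(atlas))
  diag(th) <- Inf
  z <- as.numeric(scale(map[atlas$region_id]))
  nb_mean <- vapply(seq_len(nrow(th)), function(i) {
    mean(z[order(th[i, ])[seq_len(k)]])
  }, numeric(1))
  stats::cor(z, nb_mean)
}
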
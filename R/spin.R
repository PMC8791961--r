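# One spatial permutation from a given 3x3 rotation matrix: rotate the left
# hemisphere by `rot` and the right hemisphere by its x-mirrored counterpart,
# then reassign each region to the nearest original centroid within its
# hemisphere by greedy minimal-angular-distance matching. Tie-break: the
# first minimum in column-major order (lowest rotated-region index, then
# lowest original-region index within it).
spin_assignment <- function(atlas, rot) {
  mirror <- diag(c(-1, 1, 1))
  perm <- integer(nrow(atlas))
  for (h in c("L", "R")) {
    idx <- which(atlas$hemisphere == h)
    coords <- atlas_coords(atlas)[idx, , drop = FALSE]
    Rh <- if (h == "L") rot else mirror %*% rot %*% mirror
    rotated <- coords %*% t(Rh)
    D <- angular_dist(coords, rotated)  # rows: original, cols: rotated
    n <- length(idx)
    assigned <- integer(n)
    row_free <- rep(TRUE, n); col_free <- rep(TRUE, n)
    for (step in seq_len(n)) {
      sub <- D[row_free, col_free, drop = FALSE]
      k <- which.min(sub)
      i_sub <- (k - 1L) %% nrow(sub) + 1L
      j_sub <- (k - 1L) %/% nrow(sub) + 1L
      i <- which(row_free)[i_sub]
      j <- which(col_free)[j_sub]
      assigned[i] <- j
      row_free[i] <- FALSE; col_free[j] <- FALSE
    }
    perm[idx] <- idx[assigned]
  }
  perm
}

# Uniform random rotation in SO(3): QR of a Gaussian matrix with the sign
# convention fixed, determinant forced to +1.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate spin permutations for a symmetric atlas
#'
#' Builds a spatial-permutation null for parcellated brain maps: each "spin"
#' draws a uniform random 3D rotation, rotates left-hemisphere centroids by
#' it and right-hemisphere centroids by its x-mirrored counterpart, and
#' reassigns every region to the nearest original centroid within its
#' hemisphere (greedy minimal-angular-distance matching). Because regions
#' move coherently, spun maps preserve the spatial autocorrelation of the
#' original map — the property that makes this null valid where naive
#' parametric tests are not.
#'
#' @param atlas A symmetric atlas (equal region counts per hemisphere with
#'   mirror pairing); asymmetric atlases are refused.
#' @param n_spins Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `spin_null`: `permutations` (n_spins x
#'   regions integer matrix; row k maps a vector `map` to `map[perm[k, ]]`),
#'   `region_id`, `n_spins`, `seed`.
#' @export
generate_spin_permutations <- function(atlas, n_spins, seed = 1L) {
  validate_atlas(atlas, symmetric = TRUE)
  n_spins <- assert_count(n_spins, "n_spins", min = 1L)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_spins),
             function(k) spin_assignment(atlas, random_rotation()),
             integer(nrow(atlas))))
  })
  colnames(perms) <- atlas$region_id
  out <- list(permutations = perms, region_id = atlas$region_id,
              n_spins = n_spins, seed = as.integer(seed))
  class(out) <- "spin_null"
  out
}

#' Spin-permutation correlation test between two parcellated maps
#'
#' Pearson correlation of a difference map with a receptor (or any other)
#' map, with a two-sided p-value from the spin null: the map is re-indexed
#' by every spin permutation and
#' \eqn{p = (1 + \#\{|r_{null}| \ge |r_{obs}|\}) / (1 + n_{spins})}.
#' Invariant to affine rescaling of either map.
#'
#' @param diff,map Numeric vectors in atlas order, or named vectors matched
#'   against the spin object's regions.
#' @param spins A [generate_spin_permutations()] object covering the same
#'   regions.
#' @return A list with `r_obs`, `p_spin`, `n_spins`, and the null
#'   correlations `r_null`.
#' @export
spin_correlation_test <- function(diff, map, spins) {
  stopifnot(inherits(spins, "spin_null"))
  R <- length(spins$region_id)
  pick <- function(v, what) {
    if (!is.null(names(v))) {
      if (!all(spins$region_id %in% names(v))) {
        stop(what, " does not cover the spin regions", call. = FALSE)
      }
      v <- v[spins$region_id]
    }
    if (length(v) != R) stop(what, " has the wrong length", call. = FALSE)
    as.numeric(v)
  }
  d <- pick(diff, "diff")
  m <- pick(map, "map")
  if (spins$n_spins < 100L) {
    warning("fewer than 100 spins: the spin p-value is unstable")
  }
  r_obs <- stats::cor(d, m)
  zd <- as.numeric(scale(d))
  zm <- as.numeric(scale(m))
  P <- spins$permutations
  null_mat <- matrix(zm[P], nrow(P), R)
  r_null <- as.numeric(null_mat %*% zd) / (R - 1)
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + spins$n_spins)
  list(r_obs = r_obs, p_spin = p, n_spins = spins$n_spins, r_null = r_null)
}
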
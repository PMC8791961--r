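#' Generate a symmetric synthetic parcellation atlas
#'
#' Places `n_per_hemisphere` parcel centroids quasi-uniformly on each half of
#' the unit sphere using a Fibonacci lattice, with the right hemisphere an
#' exact x-mirror of the left so that every region has a homologous
#' contralateral partner. This mirrored symmetry is what spatial-permutation
#' ("spin") null models require: rotations applied to one hemisphere can be
#' applied, mirrored, to the other.
#'
#' Lobe labels are assigned deterministically from centroid direction
#' (anterior = frontal, posterior = occipital, dorsal = parietal,
#' ventral = temporal) so that downstream summaries by lobe have something to
#' group on; they carry no other meaning.
#'
#' @param n_per_hemisphere Number of regions per hemisphere (>= 2).
#' @param seed Integer seed (kept for interface symmetry with the other
#'   generators; the lattice itself is deterministic).
#' @return A data.frame of class `atlas` with columns `region_id`,
#'   `hemisphere` ("L"/"R"), `lobe`, unit-norm centroid coordinates
#'   `x`, `y`, `z`, and `mirror_of` (the homologous region's id).
#' @examples
#' atl <- generate_atlas(34, seed = 1)
#' nrow(atl)                        # 68 regions
#' range(sqrt(atl$x^2 + atl$y^2 + atl$z^2))
#' @export
generate_atlas <- function(n_per_hemisphere, seed = 1L) {
  n <- assert_count(n_per_hemisphere, "n_per_hemisphere", min = 2L)
  # Fibonacci lattice on the hemisphere cap around the -x axis:
  # cos(theta) uniform on (0, 1), azimuth by the golden angle.
  i <- seq_len(n)
  cos_t <- 1 - (i - 0.5) / n
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  left <- cbind(x = -cos_t, y = sin_t * cos(phi), z = sin_t * sin(phi))
  right <- left
  right[, "x"] <- -right[, "x"]
  xyz <- rbind(left, right)
  hemi <- rep(c("L", "R"), each = n)
  ids <- paste0(hemi, "_", formatC(rep(i, 2), width = 3, flag = "0"))
  lobe <- ifelse(xyz[, "y"] > 0.35, "frontal",
          ifelse(xyz[, "y"] < -0.35, "occipital",
          ifelse(xyz[, "z"] > 0, "parietal", "temporal")))
  atlas <- data.frame(
    region_id = ids,
    hemisphere = hemi,
    lobe = lobe,
    x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
    mirror_of = c(ids[(n + 1):(2 * n)], ids[1:n]),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("atlas", "data.frame")
  attr(atlas, "seed") <- as.integer(seed)
  atlas
}

#' Validate an atlas object
#'
#' Checks the invariants the rest of the package relies on: unit-norm
#' centroids, involutive mirror pairing, and (optionally) equal region counts
#' per hemisphere.
#'
#' @param atlas An atlas data.frame as returned by [generate_atlas()] or read
#'   from CSV with [read_atlas_csv()].
#' @param symmetric Require equal counts per hemisphere and a complete mirror
#'   pairing (needed by the spin test).
#' @return The atlas, invisibly; errors describe the violated invariant.
#' @export
validate_atlas <- function(atlas, symmetric = TRUE) {
  need <- c("region_id", "hemisphere", "x", "y", "z", "mirror_of")
  miss <- setdiff(need, names(atlas))
  if (length(miss)) {
    stop("atlas is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(atlas$region_id)) stop("duplicate region ids in atlas",
                                           call. = FALSE)
  nrm <- sqrt(atlas$x^2 + atlas$y^2 + atlas$z^2)
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("atlas centroids must lie on the unit sphere (|norm - 1| <= 1e-9)",
         call. = FALSE)
  }
  m <- match(atlas$mirror_of, atlas$region_id)
  if (anyNA(m)) stop("mirror_of refers to unknown regions", call. = FALSE)
  if (!identical(atlas$mirror_of[m], atlas$region_id)) {
    stop("mirror pairing is not an involution", call. = FALSE)
  }
  if (symmetric) {
    tab <- table(atlas$hemisphere)
    if (length(tab) != 2L || tab[["L"]] != tab[["R"]]) {
      stop("atlas is not symmetric: unequal region counts per hemisphere",
           call. = FALSE)
    }
  }
  invisible(atlas)
}
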
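# Shared fixtures, built in code at load time. Small enough that every test
# file can lean on them without re-generating.

tiny_atlas <- generate_atlas(8, seed = 1)       # 16 regions
small_atlas <- generate_atlas(34, seed = 1)     # 68 regions (covariance-scale)

# A small three-site cohort with the default planted effects.
make_cohort <- function(atlas = small_atlas, n_sites = 3L, n = 20L,
                        seed = 42L, ...) {
  truth <- cohort_truth(atlas, n_sites = n_sites, seed = seed, ...)
  coh <- generate_cohort(atlas, truth, n, seed = seed + 1L)
  coh$truth <- truth
  coh
}

# Construct vectors with EXACT sample correlations from an orthonormal basis
# (columns orthogonal to the constant vector), so closed-form oracles hold to
# machine precision.
orthonormal_basis <- function(n, k) {
  set.seed(1)
  M <- cbind(1, matrix(rnorm(n * k), n, k))
  Q <- qr.Q(qr(M))[, -1, drop = FALSE]
  sweep(Q, 2, sqrt(colSums(Q^2)), "/")
}

# Hand-rolled BH step-up, the independent oracle for p.adjust-based paths.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
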
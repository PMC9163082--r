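# Shared fixtures: small grids keep the suite fast while preserving the
# anatomy (elongated cavity + shell, ~40% of slices near-empty).

small_spec <- function(n_phases = 9L, ef_pct = 55, seed = 1L,
                       cycle_shape = "cosine", ...) {
  synthetic_cine_spec(n_phases = n_phases, shape = c(10L, 36L, 36L),
                      edv_ul = 300, ef_pct = ef_pct, seed = seed,
                      cycle_shape = cycle_shape, ...)
}

# Voxelised ball of radius r (voxel units) centred in a cube grid.
ball_mask <- function(r = 10, pad = 4, spacing = c(1, 1, 1)) {
  n <- 2 * (r + pad) + 1
  cc <- r + pad + 1
  ax <- (seq_len(n) - cc)^2
  vox <- outer(outer(ax, ax, `+`), ax, `+`) <= r^2
  mask_stack(array(as.integer(vox), c(n, n, n)), spacing)
}

# Voxelised ellipsoid with semi-axes (a, b, c) along (z, y, x), unit spacing.
ellipsoid_mask <- function(a, b, c, pad = 3) {
  dims <- 2 * (c(a, b, c) + pad) + 1
  cc <- c(a, b, c) + pad + 1
  z2 <- ((seq_len(dims[1]) - cc[1]) / a)^2
  y2 <- ((seq_len(dims[2]) - cc[2]) / b)^2
  x2 <- ((seq_len(dims[3]) - cc[3]) / c)^2
  vox <- outer(outer(z2, y2, `+`), x2, `+`) <= 1
  mask_stack(array(as.integer(vox), dims), c(1, 1, 1))
}

random_mask <- function(shape = c(6L, 12L, 12L), n_fg = 40L, seed = 1L) {
  vox <- array(0L, shape)
  idx <- cinephase:::with_seed(seed, sample(prod(shape), n_fg))
  vox[idx] <- 1L
  mask_stack(vox, c(1, 1, 1))
}

random_pairs <- function(n, seed) {
  cinephase:::with_seed(seed, paired_ef(
    sprintf("s%02d", seq_len(n)),
    runif(n, 40, 70),
    runif(n, 40, 70)))
}
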
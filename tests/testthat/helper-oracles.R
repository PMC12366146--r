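# Independent oracles and small fixture builders shared across the suite.

# Exhaustive per-streamline ChaCo: loop over every streamline with the
# public intersection primitive and count per region. Independent of the
# cached/vectorized path inside compute_chaco.
oracle_chaco <- function(mask, connectome, n_regions) {
  hit <- vapply(connectome$streamlines,
                function(s) streamline_intersects_mask(s, mask), logical(1))
  ends <- connectome$endpoint_regions
  vapply(seq_len(n_regions), function(r) {
    conn <- ends[, 1] == r | ends[, 2] == r
    if (!any(conn)) return(NA_real_)
    sum(conn & hit) / sum(conn)
  }, numeric(1))
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(pmin(1, m * ps[i:m] / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Direct moment-formula skewness (plain and adjusted Fisher-Pearson).
oracle_skewness <- function(x, adjusted = TRUE) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  g1 <- m3 / m2^(3 / 2)
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

# Exact segment-vs-voxel intersection (slab method) against half-open voxel
# cells [c - 0.5, c + 0.5) around integer centres, in voxel coordinates.
segment_hits_cell <- function(p0, p1, centre) {
  lo <- centre - 0.5; hi <- centre + 0.5
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (abs(d[a]) < 1e-12) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return(FALSE)
    } else {
      ta <- (lo[a] - p0[a]) / d[a]
      tb <- (hi[a] - p0[a]) / d[a]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# Tiny world generator used by the randomized acceptance checks.
small_world <- function(seed, grid = 16, vox = 2, n_regions = 4,
                        n_streamlines = 60) {
  cfg <- simulation_config(grid_shape = grid, voxel_size_mm = vox,
                           n_regions = n_regions,
                           n_streamlines = n_streamlines,
                           n_patients = 2, seed = seed)
  simulate_world(cfg)
}

# Random binary mask on a world's grid (possibly empty unless min_vox > 0).
random_mask <- function(world, density = 0.05, min_vox = 0L) {
  dm <- dim(world$atlas$data)
  m <- array(as.numeric(stats::runif(prod(dm)) < density), dm)
  if (sum(m) < min_vox) m[sample(length(m), min_vox)] <- 1
  labeled_volume(m, world$atlas$affine)
}

# One-region outcome fit through the production code path; returns the row.
fit_one_region <- function(chaco_values, cohort) {
  run_region_models(matrix(chaco_values, ncol = 1), cohort, 1L)
}
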
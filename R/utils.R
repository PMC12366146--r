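# Seed derivation and RNG hygiene shared by the generators.

# Deterministic child seed from (global seed, stream index); keeps values in
# 32-bit integer range so cohorts are extensible without reshuffling earlier
# patients.
derive_seed <- function(seed, stream) {
  seed <- as.numeric(seed); stream <- as.numeric(stream)
  as.integer((seed * 48271 + stream * 16807) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state; the caller's stream is
# untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# mm coordinates of voxel centres for 1-based linear indices on a grid
voxel_mm_coords <- function(idx, dm, affine) {
  idx0 <- idx - 1L
  i <- idx0 %% dm[1]
  j <- (idx0 %/% dm[1]) %% dm[2]
  k <- idx0 %/% (dm[1] * dm[2])
  cbind(i, j, k, 1) %*% t(affine)[, 1:3]
}
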
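# Streamline-mask intersection, ChaCo scoring, cleaning, IO round trips.

test_that("streamline_intersects_mask handles empty, full and single-voxel masks", {
  dm <- c(10, 10, 10)
  aff <- diag(4)  # voxel centres at integer mm 0..9
  seg <- rbind(c(2, 5, 5), c(8, 5, 5))
  empty <- labeled_volume(array(0, dm), aff)
  full <- labeled_volume(array(1, dm), aff)
  expect_false(streamline_intersects_mask(seg, empty))
  expect_true(streamline_intersects_mask(seg, full))
  one <- array(0, dm); one[6, 6, 6] <- 1  # voxel centre (5,5,5) mm
  expect_true(streamline_intersects_mask(seg, labeled_volume(one, aff)))
  # far outside the grid
  far <- rbind(c(100, 100, 100), c(120, 100, 100))
  expect_false(streamline_intersects_mask(far, full))
})

test_that("intersection agrees with exact segment-voxel rasterization", {
  dm <- c(10, 10, 10)
  aff <- diag(4)
  set.seed(5)
  for (rep in 1:40) {
    centre <- sample(0:9, 3, replace = TRUE)
    m <- array(0, dm); m[centre[1] + 1, centre[2] + 1, centre[3] + 1] <- 1
    vol <- labeled_volume(m, aff)
    # random segments: the sampled test may miss sub-half-voxel grazings
    # but must never invent an intersection the exact slab test rejects
    p0 <- stats::runif(3, 0, 9); p1 <- stats::runif(3, 0, 9)
    if (streamline_intersects_mask(rbind(p0, p1), vol))
      expect_true(segment_hits_cell(p0, p1, centre))
    # constructed segments through the voxel interior: both must agree
    mid <- centre + stats::runif(3, -0.2, 0.2)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    q0 <- mid - dir * stats::runif(1, 1, 4)
    q1 <- mid + dir * stats::runif(1, 1, 4)
    expect_true(segment_hits_cell(q0, q1, centre))
    expect_true(streamline_intersects_mask(rbind(q0, q1), vol))
  }
})

make_chaco_fixture <- function() {
  # 12^3 grid at 1 mm; two regions; hand-placed streamlines
  dm <- c(12, 12, 12)
  aff <- diag(4)
  atlas <- array(0, dm)
  atlas[2, 2, 2] <- 1; atlas[10, 10, 10] <- 2
  sl <- list(
    rbind(c(1, 1, 1), c(9, 9, 9)),    # region 1 -> 2
    rbind(c(1, 1, 1), c(1, 9, 1)),    # region 1 -> none
    rbind(c(1, 1, 1), c(1, 1, 9)),    # region 1 -> none
    rbind(c(1, 1, 1), c(9, 1, 1))     # region 1 -> none
  )
  conn <- streamline_set(sl, rbind(c(1L, 2L), c(1L, 0L), c(1L, 0L), c(1L, 0L)))
  list(atlas = labeled_volume(atlas, aff), conn = conn, dm = dm, aff = aff)
}

test_that("compute_chaco counts disrupted streamline fractions per region", {
  fx <- make_chaco_fixture()
  # mask covering only the diagonal streamline's mid-path
  m <- array(0, fx$dm); m[6, 6, 6] <- 1
  v <- compute_chaco(labeled_volume(m, fx$aff), fx$conn, n_regions = 3)
  expect_equal(as.numeric(v), c(0.25, 1, NA))  # 1 of 4; 1 of 1; no streamline
  expect_equal(as.numeric(v), oracle_chaco(labeled_volume(m, fx$aff), fx$conn, 3))
  # empty mask: connected regions 0, unconnected NA
  v0 <- compute_chaco(labeled_volume(array(0, fx$dm), fx$aff), fx$conn, 3)
  expect_equal(as.numeric(v0), c(0, 0, NA))
  # full mask: every connected region fully disconnected
  v1 <- compute_chaco(labeled_volume(array(1, fx$dm), fx$aff), fx$conn, 3)
  expect_equal(as.numeric(v1), c(1, 1, NA))
})

test_that("compute_chaco counts a both-endpoints-in-r streamline once", {
  dm <- c(8, 8, 8); aff <- diag(4)
  sl <- list(rbind(c(1, 1, 1), c(2, 1, 1)), rbind(c(1, 1, 1), c(6, 6, 6)))
  conn <- streamline_set(sl, rbind(c(1L, 1L), c(1L, 2L)))
  m <- array(1, dm)
  v <- compute_chaco(labeled_volume(m, aff), conn, 2)
  # region 1 denominator is 2 (loop counted once), not 3
  m2 <- array(0, dm); m2[3, 2, 2] <- 1  # voxel (2,1,1) mm: only the loop
  v2 <- compute_chaco(labeled_volume(m2, aff), conn, 2)
  expect_equal(as.numeric(v2)[1], 0.5)
})

test_that("compute_chaco validates inputs", {
  fx <- make_chaco_fixture()
  bad <- labeled_volume(array(2, fx$dm), fx$aff)
  expect_error(compute_chaco(bad, fx$conn, 3), "binary")
  no_ends <- streamline_set(fx$conn$streamlines)
  expect_error(compute_chaco(labeled_volume(array(0, fx$dm), fx$aff),
                             no_ends, 3), "endpoint")
})

test_that("raw ChaCo is monotone in the mask", {
  set.seed(19)
  w <- small_world(19)
  for (rep in 1:5) {
    a <- random_mask(w, density = 0.04)
    bdat <- a$data
    bdat[sample(which(bdat == 0), 50)] <- 1  # superset
    b <- labeled_volume(bdat, a$affine)
    ca <- compute_chaco(a, w$streamlines, 4, cache = w$cache)
    cb <- compute_chaco(b, w$streamlines, 4, cache = w$cache)
    ok <- !is.na(ca) & !is.na(cb)
    expect_true(all(ca[ok] <= cb[ok] + 1e-15))
  }
})

test_that("partition ChaCo is bounded by components and their sum", {
  cfg <- simulation_config(grid_shape = 20, voxel_size_mm = 2.5, n_regions = 5,
                           n_streamlines = 120, n_patients = 4, seed = 3)
  co <- simulate_cohort(cfg)
  raw <- co$chaco$raw
  for (i in seq_len(4)) {
    wmh <- raw$wmh[i, ]; p <- raw$pwmh[i, ]; d <- raw$dwmh[i, ]
    ok <- !is.na(wmh)
    expect_true(all(wmh[ok] <= p[ok] + d[ok] + 1e-12))
    expect_true(all(wmh[ok] >= pmax(p[ok], d[ok]) - 1e-12))
  }
})

test_that("clean_chaco applies floor and ceiling with strict inequality", {
  x <- c(0.019, 0.02, 0.021, 1.0, 1.2, 0, NA, -0.001)
  out <- clean_chaco(x)
  expect_equal(out, c(0, 0.02, 0.021, 1.0, 1.0, 0, NA, 0))
  expect_equal(clean_chaco(out), out)  # idempotent
  expect_error(clean_chaco(x, floor = -0.1), "non-negative")
})

test_that("global_chaco averages present regions only", {
  expect_equal(global_chaco(c(0.2, 0.4)), 0.3)
  expect_equal(global_chaco(rep(0, 4)), 0)
  # 5-region fixture with missing entries: mean of the present four
  v <- c(0.1, NA, 0.3, 0.2, 0.4)
  expect_equal(global_chaco(v), (0.1 + 0.3 + 0.2 + 0.4) / 4)
  expect_error(global_chaco(c(NA_real_, NA_real_)), "missing")
})

test_that("streamline and ChaCo serialization round-trips deterministically", {
  w <- small_world(23, n_streamlines = 40)
  t1 <- tempfile(fileext = ".txt"); t2 <- tempfile(fileext = ".txt")
  write_streamlines_text(w$streamlines, t1)
  write_streamlines_text(w$streamlines, t2)
  expect_identical(readLines(t1), readLines(t2))
  back <- read_streamlines_text(t1)
  expect_equal(length(back), length(w$streamlines))
  expect_equal(back$streamlines[[5]], w$streamlines$streamlines[[5]],
               tolerance = 1e-6)
  k1 <- tempfile(fileext = ".tck")
  write_tck(w$streamlines, k1)
  tback <- read_tck(k1)
  expect_equal(length(tback), length(w$streamlines))
  expect_equal(tback$streamlines[[3]], w$streamlines$streamlines[[3]],
               tolerance = 1e-5)
  # endpoint reassignment from the atlas reproduces the generated labels
  re <- assign_endpoint_regions(back, w$atlas)
  expect_equal(re$endpoint_regions, w$streamlines$endpoint_regions,
               ignore_attr = TRUE)
  v <- compute_chaco(random_mask(w, 0.05), w$streamlines, 4, cache = w$cache,
                     mask_type = "wmh", patient_id = "p001")
  csvf <- tempfile(fileext = ".csv")
  write_chaco_csv(list(v), csvf)
  m <- read_chaco_csv(csvf)
  expect_equal(as.numeric(m$wmh[1, ]), as.numeric(v))
})
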
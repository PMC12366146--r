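#' Labeled voxel volume
#'
#' The common carrier for masks and atlases: a 3D array of integer labels
#' (or 0/1 for binary masks) together with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in millimetres.
#'
#' @param data 3D numeric array. Binary masks must contain only 0 and 1.
#' @param affine 4x4 numeric matrix, voxel-to-mm. Defaults to an identity
#'   spacing of 1 mm.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dims")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  d <- abs(det(affine[1:3, 1:3]))
  if (!is.finite(d) || d < .Machine$double.eps)
    stop("affine is not invertible")
  structure(list(data = data, affine = affine), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  dm <- dim(x$data)
  vs <- voxel_sizes(x)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              dm[1], dm[2], dm[3], vs[1], vs[2], vs[3]))
  labs <- unique(as.vector(x$data))
  cat("  labels:", paste(utils::head(sort(labs), 8), collapse = " "),
      if (length(labs) > 8) "...\n" else "\n")
  invisible(x)
}

#' Per-axis voxel edge lengths in mm
#' @param vol A `labeled_volume`.
#' @return Numeric length-3 vector of voxel sizes (mm).
#' @export
voxel_sizes <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

is_binary <- function(vol) {
  all(vol$data %in% c(0, 1))
}

assert_binary <- function(vol, what = "mask") {
  if (!is_binary(vol))
    stop(what, " must be binary (0/1); found other values", call. = FALSE)
  invisible(vol)
}

#' Do two volumes share a voxel grid?
#'
#' Grids match when dimensions are identical and affines agree to `tol`.
#' @param a,b `labeled_volume` objects.
#' @param tol absolute tolerance on affine entries.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$affine - b$affine) < tol)
}

assert_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share dimensions and affine",
         call. = FALSE)
  invisible(NULL)
}

#' Mask volume in millilitres
#'
#' Voxel count times voxel volume (mm^3) divided by 1000.
#'
#' @param mask binary `labeled_volume`.
#' @return volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "labeled_volume"))
  assert_binary(mask)
  vox_mm3 <- abs(det(mask$affine[1:3, 1:3]))
  sum(mask$data) * vox_mm3 / 1000
}

# 1D squared distance transform (Felzenszwalb & Huttenlocher) on a sampled
# grid with spacing w; f is the column of squared distances so far, Inf where
# no source. Returns the lower envelope of parabolas evaluated at the grid.
dt1d <- function(f, w) {
  n <- length(f)
  if (all(is.infinite(f))) return(f)
  d <- numeric(n)
  v <- integer(n)          # locations of parabolas in the envelope
  z <- numeric(n + 1L)     # boundaries between parabolas
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  x <- (seq_len(n) - 1) * w
  for (q in 2:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      if (is.infinite(f[p])) { s <- -Inf } else {
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      }
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    p <- v[k]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Euclidean distance transform in millimetres
#'
#' Exact per-voxel Euclidean distance (voxel centre to voxel centre) from
#' every voxel to the nearest voxel where `mask` is 1, honouring anisotropic
#' voxel sizes. Separable lower-envelope algorithm; requires an axis-aligned
#' affine (no rotation/shear).
#'
#' @param mask binary `labeled_volume` with at least one nonzero voxel.
#' @return 3D array of distances (mm), 0 inside the mask.
#' @export
edt_mm <- function(mask) {
  stopifnot(inherits(mask, "labeled_volume"))
  assert_binary(mask)
  if (sum(mask$data) == 0) stop("mask is empty; distance transform undefined")
  R <- mask$affine[1:3, 1:3]
  offdiag <- R; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-8 * max(abs(diag(R)))))
    stop("edt_mm requires an axis-aligned affine")
  w <- abs(diag(R))
  dm <- dim(mask$data)
  f <- array(ifelse(mask$data == 1, 0, Inf), dm)
  # axis 1
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2]))
    f[, j, k] <- dt1d(f[, j, k], w[1])
  # axis 2
  for (k in seq_len(dm[3])) for (i in seq_len(dm[1]))
    f[i, , k] <- dt1d(f[i, , k], w[2])
  # axis 3
  for (j in seq_len(dm[2])) for (i in seq_len(dm[1]))
    f[i, j, ] <- dt1d(f[i, j, ], w[3])
  sqrt(f)
}

#' Split a WMH mask into periventricular and deep components
#'
#' A WMH voxel whose Euclidean distance (mm) to the nearest ventricle voxel
#' is <= `threshold_mm` is periventricular (pWMH); the rest are deep (dWMH).
#' The boundary shell is inclusive: exactly 10 mm counts as periventricular.
#' WMH voxels lying inside the ventricle mask itself (segmentation slop) are
#' assigned to pWMH with a warning.
#'
#' @param wmh binary WMH `labeled_volume`.
#' @param ventricles binary ventricle `labeled_volume`, same grid, nonempty.
#' @param threshold_mm distance threshold in mm (default 10).
#' @param dist_mm optional precomputed `edt_mm(ventricles)` array, reused
#'   across patients that share a ventricle mask.
#' @return list with binary `labeled_volume`s `pwmh` and `dwmh`.
#' @export
split_wmh <- function(wmh, ventricles, threshold_mm = 10, dist_mm = NULL) {
  stopifnot(inherits(wmh, "labeled_volume"), inherits(ventricles, "labeled_volume"))
  assert_binary(wmh, "wmh"); assert_binary(ventricles, "ventricles")
  assert_same_grid(wmh, ventricles, "wmh and ventricle masks")
  if (sum(ventricles$data) == 0) stop("ventricle mask is empty")
  if (is.null(dist_mm)) dist_mm <- edt_mm(ventricles)
  if (!identical(dim(dist_mm), dim(wmh$data)))
    stop("dist_mm does not match the mask grid")
  inside <- wmh$data == 1 & ventricles$data == 1
  if (any(inside))
    warning(sum(inside), " WMH voxel(s) inside the ventricle mask; assigned to pWMH")
  p <- ifelse(wmh$data == 1 & dist_mm <= threshold_mm, 1, 0)
  d <- ifelse(wmh$data == 1 & dist_mm > threshold_mm, 1, 0)
  list(pwmh = labeled_volume(array(p, dim(wmh$data)), wmh$affine),
       dwmh = labeled_volume(array(d, dim(wmh$data)), wmh$affine))
}
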
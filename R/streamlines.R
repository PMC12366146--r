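#' Streamline set (reference tractogram)
#'
#' An ordered collection of polylines in world (mm) coordinates together with
#' the atlas region id of each endpoint (0 = endpoint outside every region).
#'
#' @param streamlines list of numeric matrices, each n_points x 3 (mm),
#'   n_points >= 2.
#' @param endpoint_regions integer matrix, one row per streamline, columns
#'   `start` and `end` region ids (0 = unassigned). May be `NULL` and
#'   assigned later with [assign_endpoint_regions()].
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, endpoint_regions = NULL) {
  if (!is.list(streamlines) || !length(streamlines))
    stop("`streamlines` must be a nonempty list of point matrices")
  ok <- vapply(streamlines, function(m) is.matrix(m) && ncol(m) == 3 && nrow(m) >= 2,
               logical(1))
  if (!all(ok)) stop("every streamline needs >= 2 points and 3 columns (x,y,z mm)")
  if (!is.null(endpoint_regions)) {
    endpoint_regions <- as.matrix(endpoint_regions)
    if (nrow(endpoint_regions) != length(streamlines) || ncol(endpoint_regions) != 2)
      stop("`endpoint_regions` must be an n_streamlines x 2 matrix")
    storage.mode(endpoint_regions) <- "integer"
    colnames(endpoint_regions) <- c("start", "end")
  }
  structure(list(streamlines = streamlines, endpoint_regions = endpoint_regions),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines, endpoints %s\n",
              length(x$streamlines),
              if (is.null(x$endpoint_regions)) "unassigned" else "assigned"))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Resample a polyline at a maximum step length
#'
#' Keeps all original vertices and inserts points along each segment so that
#' consecutive samples are at most `step` mm apart. Deterministic.
#'
#' @param points n x 3 matrix of vertices (mm).
#' @param step maximum spacing in mm (> 0).
#' @return m x 3 matrix of samples, m >= n.
#' @export
resample_polyline <- function(points, step) {
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) >= 2, step > 0)
  pieces <- vector("list", nrow(points) - 1L)
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = nseg + 1L)
    t <- t[-length(t)]  # final vertex comes from the next piece / appended below
    pieces[[i]] <- cbind(a[1] + t * (b[1] - a[1]),
                         a[2] + t * (b[2] - a[2]),
                         a[3] + t * (b[3] - a[3]))
  }
  rbind(do.call(rbind, pieces), points[nrow(points), , drop = FALSE])
}

# Map mm points to 0-based voxel indices (rounded to nearest centre, i.e.
# half-open voxel cells). Returns an n x 3 integer matrix; rows may fall
# outside the grid.
points_to_voxels <- function(points, affine) {
  inv <- tryCatch(solve(affine), error = function(e)
    stop("affine is not invertible", call. = FALSE))
  v <- cbind(points, 1) %*% t(inv)
  matrix(as.integer(round(v[, 1:3])), ncol = 3)
}

# Deduplicated 1-based linear voxel indices that a streamline visits in a
# grid of dims `dm`; out-of-grid samples are dropped.
streamline_voxel_indices <- function(points, affine, dm, step) {
  s <- resample_polyline(points, step)
  ix <- points_to_voxels(s, affine)
  keep <- ix[, 1] >= 0L & ix[, 1] < dm[1] &
          ix[, 2] >= 0L & ix[, 2] < dm[2] &
          ix[, 3] >= 0L & ix[, 3] < dm[3]
  ix <- ix[keep, , drop = FALSE]
  if (!nrow(ix)) return(integer(0))
  unique(ix[, 1] + dm[1] * (ix[, 2] + dm[2] * ix[, 3]) + 1L)
}

#' Precompute streamline voxel visits on a grid
#'
#' Per streamline, the set of voxels (1-based linear indices) its half-voxel
#' resampling visits on the grid of `template`. Reusing the cache makes
#' repeated ChaCo evaluations against different masks on the same grid cheap.
#'
#' @param connectome a `streamline_set`.
#' @param template a `labeled_volume` defining grid and affine.
#' @return list of integer vectors, one per streamline.
#' @export
streamline_voxel_cache <- function(connectome, template) {
  stopifnot(inherits(connectome, "streamline_set"),
            inherits(template, "labeled_volume"))
  step <- 0.5 * min(voxel_sizes(template))
  dm <- dim(template$data)
  lapply(connectome$streamlines, streamline_voxel_indices,
         affine = template$affine, dm = dm, step = step)
}

#' Does a streamline pass through a mask?
#'
#' True iff any sample of the polyline, resampled at half the minimum voxel
#' edge, falls in a voxel where the mask is 1. Points outside the grid never
#' intersect.
#'
#' @param streamline n x 3 matrix of points (mm).
#' @param mask binary `labeled_volume`.
#' @return logical scalar.
#' @export
streamline_intersects_mask <- function(streamline, mask) {
  stopifnot(inherits(mask, "labeled_volume"))
  assert_binary(mask)
  step <- 0.5 * min(voxel_sizes(mask))
  idx <- streamline_voxel_indices(streamline, mask$affine, dim(mask$data), step)
  if (!length(idx)) return(FALSE)
  any(mask$data[idx] == 1)
}

#' Assign endpoint regions from an atlas
#'
#' Looks up the atlas label at each streamline's first and last point
#' (nearest-voxel). 0 marks endpoints outside the grid or in background.
#'
#' @param connectome a `streamline_set`.
#' @param atlas integer-labeled `labeled_volume`.
#' @return the `streamline_set` with `endpoint_regions` filled in.
#' @export
assign_endpoint_regions <- function(connectome, atlas) {
  stopifnot(inherits(connectome, "streamline_set"), inherits(atlas, "labeled_volume"))
  dm <- dim(atlas$data)
  ends <- t(vapply(connectome$streamlines, function(m) {
    ix <- points_to_voxels(m[c(1L, nrow(m)), , drop = FALSE], atlas$affine)
    vapply(1:2, function(r) {
      v <- ix[r, ]
      if (any(v < 0L) || any(v >= dm)) return(0L)
      as.integer(atlas$data[v[1] + 1L, v[2] + 1L, v[3] + 1L])
    }, integer(1))
  }, integer(2)))
  streamline_set(connectome$streamlines, ends)
}

## ---- serialization ----------------------------------------------------

#' Write streamlines in the plain-text fixture dialect
#'
#' One streamline per block, one "x y z" line per point, blank line between
#' blocks. Endpoint assignments are not stored; reassign from an atlas.
#'
#' @param connectome a `streamline_set`.
#' @param path output path.
#' @param digits significant digits to print.
#' @export
write_streamlines_text <- function(connectome, path, digits = 10) {
  stopifnot(inherits(connectome, "streamline_set"))
  blocks <- vapply(connectome$streamlines, function(m) {
    paste(apply(format(m, digits = digits, trim = TRUE, scientific = FALSE),
                1, paste, collapse = " "), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read streamlines from the plain-text fixture dialect
#' @param path input path.
#' @return a `streamline_set` with unassigned endpoints.
#' @export
read_streamlines_text <- function(path) {
  lines <- readLines(path)
  grp <- cumsum(!nzchar(trimws(lines)))
  keep <- nzchar(trimws(lines))
  sl <- lapply(split(lines[keep], grp[keep]), function(b) {
    m <- do.call(rbind, lapply(strsplit(trimws(b), "[[:space:]]+"),
                               function(p) as.numeric(p)))
    if (ncol(m) != 3) stop("expected 3 coordinates per line in ", path)
    m
  })
  names(sl) <- NULL
  streamline_set(sl)
}

#' Write streamlines as a TCK (MRtrix) track file
#'
#' Float32 little-endian triplets, NaN-separated, Inf-terminated, after a
#' text header.
#'
#' @param connectome a `streamline_set`.
#' @param path output path (conventionally `.tck`).
#' @export
write_tck <- function(connectome, path) {
  stopifnot(inherits(connectome, "streamline_set"))
  n <- length(connectome$streamlines)
  # the offset appears inside the header; iterate to a fixed point
  offset <- 100L
  for (i in 1:3) {
    header <- sprintf("mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n",
                      n, offset)
    if (nchar(header, type = "bytes") == offset) break
    offset <- nchar(header, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (m in connectome$streamlines) {
    writeBin(as.double(t(m)), con, size = 4L, endian = "little")
    writeBin(as.double(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.double(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK (MRtrix) track file
#' @param path input path.
#' @return a `streamline_set` with unassigned endpoints.
#' @export
read_tck <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  end_pos <- grepRaw("END\n", bytes, fixed = TRUE)
  if (!length(end_pos)) stop("TCK header without END in ", path)
  head_txt <- rawToChar(bytes[seq_len(end_pos + 3L)])
  if (!grepl("^mrtrix tracks", head_txt)) stop(path, " is not a TCK file")
  header_lines <- strsplit(head_txt, "\n", fixed = TRUE)[[1]]
  offset <- NA_integer_
  datatype <- "Float32LE"
  for (ln in header_lines) {
    if (grepl("^file:", ln))
      offset <- as.integer(sub("^file:\\s*\\.\\s+", "", ln))
    if (grepl("^datatype:", ln))
      datatype <- trimws(sub("^datatype:", "", ln))
  }
  if (datatype != "Float32LE") stop("unsupported TCK datatype ", datatype)
  if (is.na(offset)) stop("TCK header missing file offset in ", path)
  raw_vals <- readBin(bytes[(offset + 1L):length(bytes)], "double",
                      n = (length(bytes) - offset) %/% 4L, size = 4L,
                      endian = "little")
  pts <- matrix(raw_vals, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(pts[, 1])
  is_end <- is.infinite(pts[, 1])
  if (any(is_end)) pts <- pts[seq_len(which(is_end)[1] - 1L), , drop = FALSE]
  is_sep <- is.nan(pts[, 1])
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)]))
  sl <- lapply(split.data.frame(pts[!is_sep, , drop = FALSE], grp[!is_sep]),
               function(m) { dimnames(m) <- NULL; m })
  names(sl) <- NULL
  streamline_set(sl)
}
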
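# Minimal NIfTI-1 I/O. Single-file .nii / .nii.gz, sform affine, the
# datatypes masks and atlases need. Written because no NIfTI reader ships
# with the supported R stack; layout follows the nifti1.h field order.

nifti_read_spec <- list(
  `2`  = list(what = "int",    size = 1L, signed = FALSE),
  `4`  = list(what = "int",    size = 2L, signed = TRUE),
  `8`  = list(what = "int",    size = 4L, signed = TRUE),
  `16` = list(what = "double", size = 4L, signed = TRUE),
  `64` = list(what = "double", size = 8L, signed = TRUE)
)

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Assemble the 348-byte NIfTI-1 header in a raw buffer.
build_nifti_header <- function(dm, vs, affine, datatype, bitpix) {
  hdr <- raw(352)  # header + 4-byte extension flag
  put <- function(off, bytes) {
    hdr[(off + 1):(off + length(bytes))] <<- bytes
    invisible(NULL)
  }
  i16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  i32 <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "little")
  f32 <- function(v) writeBin(as.double(v), raw(), size = 4L, endian = "little")
  put(0, i32(348L))                            # sizeof_hdr
  put(40, i16(c(3L, dm, 1L, 1L, 1L, 1L)))      # dim[8]
  put(70, i16(datatype))
  put(72, i16(bitpix))
  put(76, f32(c(1, vs, 0, 0, 0, 0)))           # pixdim[8], qfac = 1
  put(108, f32(352))                           # vox_offset
  put(112, f32(1)); put(116, f32(0))           # scl_slope, scl_inter
  put(252, i16(0L))                            # qform_code
  put(254, i16(1L))                            # sform_code
  put(280, f32(affine[1, ]))                   # srow_x
  put(296, f32(affine[2, ]))                   # srow_y
  put(312, f32(affine[3, ]))                   # srow_z
  put(344, charToRaw("n+1"))                   # magic (nul-padded)
  hdr
}

#' Write a volume as NIfTI-1
#'
#' Single-file `.nii` (or gzipped `.nii.gz`), affine stored in the sform.
#' Integer-valued data (atlases, masks) are stored as int32, everything else
#' as float64.
#'
#' @param vol a `labeled_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  dat <- vol$data
  integral <- all(dat == round(dat)) && max(abs(dat), 0) < 2^31 - 1
  con <- open_conn(path, "wb")
  on.exit(close(con))
  hdr <- build_nifti_header(dim(dat), voxel_sizes(vol), vol$affine,
                            datatype = if (integral) 8L else 64L,
                            bitpix = if (integral) 32L else 64L)
  writeBin(hdr, con)
  if (integral) {
    writeBin(as.integer(dat), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(dat), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file `.nii` / `.nii.gz` with datatype uint8, int16, int32,
#' float32 or float64. The affine is taken from the sform when set,
#' otherwise a diagonal affine is built from `pixdim`. Slope/intercept
#' scaling is applied when present.
#'
#' @param path file path.
#' @return a `labeled_volume`.
#' @export
read_nifti <- function(path) {
  con <- open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size, signed = TRUE, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian = "little") != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian = "big") != 348L)
      stop(path, " is not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": unsupported magic '", magic, "'")
  dims <- rd(40, "integer", 8, 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3D volume, got ", ndim, " dims")
  dm <- dims[2:4]
  if (ndim > 3L && any(dims[5:(ndim + 1)] > 1L))
    stop("4D+ volumes are not supported")
  datatype <- rd(70, "integer", 1, 2, endian = endian)
  spec <- nifti_read_spec[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76, "double", 8, 4, endian = endian)
  vox_offset <- rd(108, "double", 1, 4, endian = endian)
  slope <- rd(112, "double", 1, 4, endian = endian)
  inter <- rd(116, "double", 1, 4, endian = endian)
  sform_code <- rd(254, "integer", 1, 2, endian = endian)
  n <- prod(dm)
  # skip from end of header to the data offset
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  what <- if (spec$what == "int") "integer" else "double"
  dat <- readBin(con, what, n = n, size = spec$size, signed = spec$signed,
                 endian = endian)
  if (length(dat) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    dat <- dat * slope + inter
  if (sform_code > 0L) {
    affine <- rbind(matrix(rd(280, "double", 12, 4, endian = endian),
                           nrow = 3, byrow = TRUE),
                    c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  labeled_volume(array(dat, dm), affine)
}
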
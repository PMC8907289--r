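## Minimal NIfTI-1 I/O.
## No NIfTI package ships with the supported toolchain, and the format's
## single-file variant is a fixed 348-byte header + voxel payload, so the
## subset needed here (3-D scalar volumes, sform affine, optional gzip) is
## implemented directly with readBin/writeBin.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Supports single-file `.nii` / `.nii.gz` with datatypes uint8, int16,
#' int32, float32, float64. The affine is taken from the sform when
#' `sform_code > 0`, else from the qform quaternion, else a diagonal
#' affine from `pixdim`. Scaling via `scl_slope`/`scl_inter` is applied.
#'
#' @param path file path.
#' @param role channel role for the returned [vol3d()] (`"T1CE"`, `"FLAIR"`
#'   or `"MASK"`).
#' @return a [vol3d()].
#' @export
read_volume <- function(path, role = "T1CE") {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("read_volume: truncated NIfTI header")
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr_be <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = "big")
    if (sizeof_hdr_be == 348L) endian <- "big"
    else stop("read_volume: not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size,
            endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_volume: not a NIfTI-1 file (bad magic)")
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim != 3L) {
    # a trailing 4th dimension of size 1 still describes a 3-D payload
    if (ndim == 4L && dims[5] == 1L) ndim <- 3L
    else stop("read_volume: expected a 3-D volume, got ", ndim, " dimensions")
  }
  shape <- dims[2:4]
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("read_volume: unsupported NIfTI datatype ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  affine <- NULL
  if (sform_code > 0L) {
    srow <- rbind(rd(280, "double", 4, 4), rd(296, "double", 4, 4),
                  rd(312, "double", 4, 4))
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- rd(256, "double", 6, 4)  # quatern_b,c,d, qoffset_x,y,z
    b <- q[1]; c <- q[2]; d <- q[3]
    a2 <- 1 - b * b - c * c - d * d
    a <- sqrt(max(0, a2))
    R <- matrix(c(
      a*a+b*b-c*c-d*d, 2*(b*c-a*d),     2*(b*d+a*c),
      2*(b*c+a*d),     a*a+c*c-b*b-d*d, 2*(c*d-a*b),
      2*(b*d-a*c),     2*(c*d+a*b),     a*a+d*d-b*b-c*c), 3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    R[, 3] <- R[, 3] * qfac
    affine <- diag(4)
    affine[1:3, 1:3] <- R %*% diag(spacing)
    affine[1:3, 4] <- q[4:6]
  } else {
    affine <- diag(c(spacing, 1))
  }
  n_vox <- prod(shape)
  # payload starts at vox_offset; header read consumed 348 bytes so far
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n_vox, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n_vox) stop("read_volume: truncated NIfTI payload")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 &&
                                                  scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vol3d(array(vals, dim = shape), spacing = spacing, affine = affine,
        role = role)
}

#' Write a 3-D volume as NIfTI-1
#'
#' Images are stored as float32 and masks as uint8, single-file format with
#' the affine in the sform. `.gz` paths are gzip-compressed. Round-tripping
#' preserves mask values exactly and image values to float32 precision
#' (bit-exact for values representable in float32).
#'
#' @param vol a [vol3d()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol3d"))
  dirp <- dirname(path)
  if (!dir.exists(dirp)) stop("write_volume: directory does not exist: ", dirp)
  is_mask <- vol$role == "MASK"
  datatype <- if (is_mask) 2L else 16L
  bitpix <- if (is_mask) 8L else 32L
  shape <- dim(vol$values)

  hdr <- raw(348)
  put <- function(hdr, off, x, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, 348L, 4)                         # sizeof_hdr
  hdr <- put(hdr, 39, 114L, 1)                        # dim_info unused; regular='r'
  hdr <- put(hdr, 40, c(3L, shape, 1L, 1L, 1L, 1L), 2)  # dim
  hdr <- put(hdr, 70, datatype, 2)                    # datatype
  hdr <- put(hdr, 72, bitpix, 2)                      # bitpix
  hdr <- put(hdr, 76, c(1, vol$spacing, 0, 0, 0, 0), 4, "double")  # pixdim
  hdr <- put(hdr, 108, 352, 4, "double")              # vox_offset
  hdr <- put(hdr, 112, 1, 4, "double")                # scl_slope
  hdr <- put(hdr, 116, 0, 4, "double")                # scl_inter
  hdr <- put(hdr, 252, 0L, 2)                         # qform_code
  hdr <- put(hdr, 254, 1L, 2)                         # sform_code
  hdr <- put(hdr, 280, vol$affine[1, ], 4, "double")  # srow_x
  hdr <- put(hdr, 296, vol$affine[2, ], 4, "double")  # srow_y
  hdr <- put(hdr, 312, vol$affine[3, ], 4, "double")  # srow_z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))      # magic

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                               # extension flag
  if (is_mask) {
    writeBin(as.integer(round(as.vector(vol$values))), con, size = 1)
  } else {
    writeBin(as.numeric(as.vector(vol$values)), con, size = 4,
             endian = "little")
  }
  invisible(path)
}
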
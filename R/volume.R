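#' 3-D scalar volume with voxel geometry
#'
#' A `vol3d` carries one MR channel (or a binary mask) on a regular 3-D grid:
#' the voxel values, the per-axis voxel spacing in mm, and a 4x4 affine
#' mapping 0-based voxel indices (i, j, k, 1) to world coordinates in mm.
#'
#' @param values numeric 3-D array.
#' @param spacing numeric length-3, voxel size in mm, strictly positive.
#' @param affine 4x4 grid-index-to-world matrix; defaults to a diagonal
#'   affine built from `spacing` with the origin at voxel (0,0,0).
#' @param role one of `"T1CE"`, `"FLAIR"`, `"MASK"`. MASK volumes must
#'   contain only 0 and 1.
#' @return an object of class `vol3d`.
#' @export
vol3d <- function(values, spacing = c(1, 1, 1), affine = NULL,
                  role = c("T1CE", "FLAIR", "MASK")) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("vol3d: `values` must be a 3-D array, got ",
         paste(dim(values), collapse = "x"), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("vol3d: spacing must be 3 strictly positive finite values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("vol3d: affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("vol3d: affine is singular")
  if (role == "MASK") {
    u <- unique(as.vector(values))
    if (!all(u %in% c(0, 1)))
      stop("vol3d: MASK volume contains values outside {0, 1}")
    storage.mode(values) <- "double"
  }
  structure(list(values = values, spacing = spacing, affine = affine,
                 role = role),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d %s  %s voxels  spacing %s mm>\n", x$role,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$values)

is_mask <- function(vol) inherits(vol, "vol3d") && vol$role == "MASK"

#' Tumor volume of a binary mask in cubic millimetres
#'
#' Number of foreground voxels times the voxel volume derived from spacing.
#'
#' @param mask a `vol3d` with role MASK.
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "vol3d"))
  if (mask$role != "MASK") stop("mask_volume_mm3: volume role is not MASK")
  v <- as.vector(mask$values)
  if (!all(v %in% c(0, 1))) stop("mask_volume_mm3: non-binary mask values")
  sum(v) * prod(mask$spacing)
}

#' Ratio of enhancing tumor volume to FLAIR-hyperintense volume
#'
#' R = V_T1CE / V_T2FLAIR, where each volume is the foreground volume of the
#' contoured mask on that sequence. Low R means the edema-like FLAIR region
#' far exceeds the enhancing core.
#'
#' @param t1ce_mask,flair_mask binary `vol3d` masks (role MASK).
#' @return dimensionless ratio.
#' @export
compute_r_ratio <- function(t1ce_mask, flair_mask) {
  v1 <- mask_volume_mm3(t1ce_mask)
  v2 <- mask_volume_mm3(flair_mask)
  if (v1 <= 0) stop("compute_r_ratio: empty T1-CE mask")
  if (v2 <= 0) stop("compute_r_ratio: empty FLAIR mask (undefined ratio)")
  v1 / v2
}

## world <-> voxel helpers: ijk are 0-based, rows of an n x 3 matrix
voxel_to_world <- function(ijk, affine) {
  h <- cbind(ijk, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(xyz, affine) {
  h <- cbind(xyz, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

## gather with zero fill outside [0, dim-1]
gather_trilinear <- function(values, idx) {
  d <- dim(values)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  acc <- numeric(nrow(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3] &
      w > 0
    if (any(ok)) {
      lin <- xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok]) + 1
      acc[ok] <- acc[ok] + w[ok] * values[lin]
    }
  }
  acc
}

gather_nearest <- function(values, idx) {
  d <- dim(values)
  xi <- round(idx[, 1]); yi <- round(idx[, 2]); zi <- round(idx[, 3])
  out <- numeric(nrow(idx))
  ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
  if (any(ok)) {
    lin <- xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok]) + 1
    out[ok] <- values[lin]
  }
  out
}

grid_index_matrix <- function(shape) {
  as.matrix(expand.grid(i = 0:(shape[1] - 1),
                        j = 0:(shape[2] - 1),
                        k = 0:(shape[3] - 1)))
}

#' Resample a volume onto the grid of a reference volume
#'
#' Values are interpolated in world space: each reference voxel centre is
#' mapped through the reference affine to mm coordinates and back through the
#' moving volume's inverse affine. Voxels falling outside the moving volume's
#' field of view are filled with 0. Masks must use nearest-neighbour
#' interpolation so the output stays binary.
#'
#' @param moving,reference `vol3d` objects.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return a `vol3d` on the reference grid (spacing/affine of the reference,
#'   role of the moving volume).
#' @export
resample_to_reference <- function(moving, reference,
                                  interp = c("trilinear", "nearest")) {
  stopifnot(inherits(moving, "vol3d"), inherits(reference, "vol3d"))
  interp <- match.arg(interp)
  if (moving$role == "MASK" && interp != "nearest")
    stop("resample_to_reference: MASK volumes must use nearest interpolation")
  shape <- dim(reference$values)
  ijk <- grid_index_matrix(shape)
  xyz <- voxel_to_world(ijk, reference$affine)
  midx <- world_to_voxel(xyz, moving$affine)
  vals <- if (interp == "trilinear") gather_trilinear(moving$values, midx)
          else gather_nearest(moving$values, midx)
  d <- dim(moving$values)
  inside <- midx[, 1] > -0.5 & midx[, 1] < d[1] - 0.5 &
            midx[, 2] > -0.5 & midx[, 2] < d[2] - 0.5 &
            midx[, 3] > -0.5 & midx[, 3] < d[3] - 0.5
  if (!any(inside))
    warning("resample_to_reference: fields of view do not overlap; ",
            "output is all fill values")
  out <- array(vals, dim = shape)
  vol3d(out, spacing = reference$spacing, affine = reference$affine,
        role = moving$role)
}

#' Resample a volume to an isotropic grid
#'
#' Builds a target grid with `target_mm` spacing on every axis that preserves
#' the world extent of the input to within one voxel per axis, then resamples.
#'
#' @param vol a `vol3d`.
#' @param target_mm target isotropic voxel size in mm (default 1).
#' @param interp `"trilinear"` or `"nearest"` (masks require nearest).
#' @return a `vol3d` with isotropic spacing `target_mm`.
#' @export
resample_isotropic <- function(vol, target_mm = 1.0,
                               interp = c("trilinear", "nearest")) {
  stopifnot(inherits(vol, "vol3d"))
  interp <- match.arg(interp)
  if (!is.finite(target_mm) || target_mm <= 0)
    stop("resample_isotropic: target_mm must be > 0")
  shape <- dim(vol$values)
  extent <- shape * vol$spacing
  new_shape <- pmax(1L, as.integer(round(extent / target_mm)))
  # preserve axis directions; rescale direction columns to the target length
  dirs <- vol$affine[1:3, 1:3]
  dirn <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  new_aff <- diag(4)
  new_aff[1:3, 1:3] <- dirn * target_mm
  new_aff[1:3, 4] <- vol$affine[1:3, 4]
  ref <- vol3d(array(0, dim = new_shape), spacing = rep(target_mm, 3),
               affine = new_aff, role = "T1CE")
  out <- resample_to_reference(vol, ref, interp = interp)
  out$role <- vol$role
  out
}

## mask centroid in 0-based voxel coordinates (mean of foreground indices)
mask_centroid <- function(values) {
  idx <- which(values > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask_centroid: empty mask")
  colMeans(idx) - 1
}

## round-half-down: ties go toward the lower index
round_half_down <- function(x) ceiling(x - 0.5)

#' Crop a two-channel region of interest centred on the tumor
#'
#' Extracts a fixed-shape window centred on the mask centroid from both
#' channels with one shared crop origin, zero-padding where the window falls
#' outside the source grid. The centroid is rounded to the nearest voxel with
#' ties toward the lower index; the window is half-open
#' `[origin, origin + shape)`.
#'
#' @param t1ce,flair `vol3d` image channels on one shared grid.
#' @param mask `vol3d` MASK used for centring (typically the union of the
#'   T1-CE and FLAIR contours).
#' @param target_shape integer length-3 output shape.
#' @param masked if TRUE, multiply both channels by the mask (zero out
#'   non-tumor context) before cropping.
#' @return a `roi_tensor`: list with `values` (4-D array x,y,z,channel with
#'   channel 1 = T1CE, 2 = FLAIR), `crop_origin` (0-based voxel offset) and
#'   `source_subject`.
#' @export
crop_to_roi <- function(t1ce, flair, mask, target_shape,
                        subject_id = NA_character_, masked = FALSE) {
  stopifnot(inherits(t1ce, "vol3d"), inherits(flair, "vol3d"),
            inherits(mask, "vol3d"))
  if (!identical(dim(t1ce$values), dim(flair$values)) ||
      !identical(dim(t1ce$values), dim(mask$values)))
    stop("crop_to_roi: volumes must share one grid")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) == 1L) target_shape <- rep(target_shape, 3L)
  cen <- mask_centroid(mask$values)
  # window centred on the centroid: origin = centroid - (shape-1)/2,
  # rounded to the nearest voxel with ties toward the lower index
  origin <- as.integer(round_half_down(cen - (target_shape - 1) / 2))
  vt <- t1ce$values
  vf <- flair$values
  if (masked) {
    vt <- vt * mask$values
    vf <- vf * mask$values
  }
  out <- array(0, dim = c(target_shape, 2L))
  src_dim <- dim(vt)
  # overlap of [origin, origin+shape) with [0, src_dim) per axis (0-based)
  lo <- pmax(origin, 0L)
  hi <- pmin(origin + target_shape, src_dim)
  if (all(hi > lo)) {
    sx <- (lo[1] + 1):hi[1]; sy <- (lo[2] + 1):hi[2]; sz <- (lo[3] + 1):hi[3]
    dx <- (lo[1] - origin[1] + 1):(hi[1] - origin[1])
    dy <- (lo[2] - origin[2] + 1):(hi[2] - origin[2])
    dz <- (lo[3] - origin[3] + 1):(hi[3] - origin[3])
    out[dx, dy, dz, 1] <- vt[sx, sy, sz]
    out[dx, dy, dz, 2] <- vf[sx, sy, sz]
  }
  structure(list(values = out, crop_origin = origin,
                 source_subject = subject_id),
            class = "roi_tensor")
}

#' @export
print.roi_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<roi_tensor %s  origin (%s)  subject %s>\n",
              paste(d[1:3], collapse = "x"),
              paste(x$crop_origin, collapse = ","), x$source_subject))
  invisible(x)
}

#' Z-score intensity normalization over the support
#'
#' Standardizes a channel to mean 0, SD 1 over its support voxels (the
#' foreground mask if given, otherwise all nonzero voxels); voxels outside
#' the support are set to 0. A constant channel maps to all zeros.
#'
#' @param vol a `vol3d` image channel.
#' @param mask optional `vol3d` MASK defining the support.
#' @return normalized `vol3d`.
#' @export
normalize_intensity <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "vol3d"))
  v <- vol$values
  if (any(!is.finite(v))) stop("normalize_intensity: non-finite values")
  support <- if (is.null(mask)) v != 0 else mask$values > 0
  out <- array(0, dim = dim(v))
  if (any(support)) {
    s <- v[support]
    mu <- mean(s)
    sdv <- stats::sd(s)
    if (is.finite(sdv) && sdv > 1e-12) out[support] <- (s - mu) / sdv
  }
  vol3d(out, spacing = vol$spacing, affine = vol$affine, role = vol$role)
}
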
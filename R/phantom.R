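PHANTOM_LOCATIONS <- c("anterior/middle fossa", "convexity",
                       "falx/parasagittal", "posterior fossa",
                       "lateral ventricle")

#' Synthetic two-channel tumor phantom configuration
#'
#' The phantom emulates the data regime of a 96-subject meningioma cohort:
#' an enhancing tumor ellipsoid in channel 1 (T1-CE-like), an edema-like
#' halo in channel 2 (FLAIR-like) whose volume is set by an independently
#' drawn ratio R = V_T1CE / V_T2FLAIR, a grade-dependent texture and
#' boundary-spiculation signal concentrated in channel 1, and a weak
#' grade-dependent intensity signal in channel 2. Because R is drawn
#' independently of grade, edema volume is a confound: it tracks lesion
#' size, not class.
#'
#' @param grid_shape voxels per axis (default 64).
#' @param spacing_mm isotropic voxel size in mm (default 1).
#' @param tumor_radius_range_mm min/max mean tumor radius in mm.
#' @param grade1_heterogeneity,grade2_heterogeneity intratumoral texture SD
#'   per class (grade II must be >= grade I).
#' @param grade2_spiculation boundary-perturbation amplitude added for
#'   Grade II (relative radius units).
#' @param flair_signal_weight magnitude of the weak grade-dependent signal
#'   in channel 2 (small relative to the channel-1 effect).
#' @param r_mean,r_sd,r_min,r_max truncated-normal parameters of the R
#'   distribution; defaults 0.83, 0.50, 0.07, 3.19.
#' @param noise_sd additive Gaussian noise SD applied to both channels.
#' @param class_probs probabilities of Grade I vs II (default 55/96, 41/96).
#' @param location_probs categorical weights over the five location labels
#'   (default 43:20:18:13:2); cosmetic metadata for stratified evaluation.
#' @param seed integer seed used by [generate_cohort()].
#' @return a `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L), spacing_mm = 1.0,
                           tumor_radius_range_mm = c(8, 14),
                           grade1_heterogeneity = 0.10,
                           grade2_heterogeneity = 0.30,
                           grade2_spiculation = 0.25,
                           flair_signal_weight = 0.05,
                           r_mean = 0.83, r_sd = 0.50,
                           r_min = 0.07, r_max = 3.19,
                           noise_sd = 0.05,
                           class_probs = c(I = 55, II = 41) / 96,
                           location_probs =
                             stats::setNames(c(43, 20, 18, 13, 2) / 96,
                                             PHANTOM_LOCATIONS),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  nums <- c(spacing_mm, tumor_radius_range_mm, grade1_heterogeneity,
            grade2_heterogeneity, grade2_spiculation, flair_signal_weight,
            r_mean, r_sd, r_min, r_max, noise_sd, class_probs,
            location_probs)
  if (any(!is.finite(nums)))
    stop("phantom_config: non-finite configuration parameter")
  if (grade2_heterogeneity < grade1_heterogeneity)
    stop("phantom_config: grade2_heterogeneity must be >= ",
         "grade1_heterogeneity")
  if (!(r_min > 0 && r_min < r_max))
    stop("phantom_config: need 0 < r_min < r_max")
  if (r_mean < r_min || r_mean > r_max)
    stop("phantom_config: r_mean must lie in [r_min, r_max]")
  if (r_sd < 0) stop("phantom_config: r_sd must be >= 0")
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("phantom_config: class_probs must sum to 1")
  if (abs(sum(location_probs) - 1) > 1e-9)
    stop("phantom_config: location_probs must sum to 1")
  if (tumor_radius_range_mm[1] <= 0 ||
      tumor_radius_range_mm[2] < tumor_radius_range_mm[1])
    stop("phantom_config: bad tumor_radius_range_mm")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tumor_radius_range_mm = tumor_radius_range_mm,
                 grade1_heterogeneity = grade1_heterogeneity,
                 grade2_heterogeneity = grade2_heterogeneity,
                 grade2_spiculation = grade2_spiculation,
                 flair_signal_weight = flair_signal_weight,
                 r_mean = r_mean, r_sd = r_sd, r_min = r_min, r_max = r_max,
                 noise_sd = noise_sd, class_probs = class_probs,
                 location_probs = location_probs, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Draw one volume ratio R from the truncated normal
#'
#' Rejection sampling from Normal(r_mean, r_sd) restricted to
#' `[r_min, r_max]`. With `r_sd = 0` the degenerate value `r_mean` is
#' returned. Uses the current R RNG state.
#'
#' @param config a [phantom_config()].
#' @param n number of draws.
#' @return numeric vector of draws in `[r_min, r_max]`.
#' @export
sample_r_ratio <- function(config, n = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$r_sd == 0) return(rep(config$r_mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(max(n - length(out), 16L), config$r_mean,
                         config$r_sd)
    out <- c(out, cand[cand >= config$r_min & cand <= config$r_max])
  }
  out[seq_len(n)]
}

## low-frequency directional perturbation field on the unit sphere:
## sum of J random cosine waves, approximately N(0, 1) marginally
make_spic_field <- function(J = 6L) {
  u <- matrix(stats::rnorm(3 * J), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  om <- stats::runif(J, 2, 5)
  ph <- stats::runif(J, 0, 2 * pi)
  a <- stats::rnorm(J)
  function(dirs) {
    # dirs: n x 3 unit vectors
    acc <- 0
    for (j in seq_len(J))
      acc <- acc + a[j] * cos(om[j] * (dirs %*% u[j, ]) + ph[j])
    as.vector(acc) * sqrt(2 / J)
  }
}

#' Generate one synthetic two-channel tumor subject
#'
#' Channel 1 holds a randomly placed tumor ellipsoid with intratumoral
#' Gaussian texture (SD set by the class heterogeneity) and, for Grade II,
#' extra boundary spiculation. Channel 2 holds an edema-like halo grown (or
#' shrunk) around the tumor in the ellipsoid metric until its voxel count is
#' `V_T1CE / r` for an independently drawn ratio r, plus a weak
#' grade-dependent intensity component. Masks are derived before noise is
#' added. Uses the current R RNG state.
#'
#' @param config a [phantom_config()].
#' @param grade `"I"` or `"II"`.
#' @param subject_id id string stored with the subject.
#' @return a subject: list with `subject_id`, `t1ce`, `flair`, `t1ce_mask`,
#'   `flair_mask` ([vol3d()]s), `grade`, `location`, `r_ratio` (mask-derived).
#' @export
generate_subject <- function(config, grade = c("I", "II"),
                             subject_id = "s001") {
  stopifnot(inherits(config, "phantom_config"))
  grade <- match.arg(grade)
  shape <- config$grid_shape
  sp <- config$spacing_mm
  r <- sample_r_ratio(config)
  spic_amp <- 0.05 + if (grade == "II") config$grade2_spiculation else 0
  het <- if (grade == "II") config$grade2_heterogeneity
         else config$grade1_heterogeneity
  field <- make_spic_field()

  max_mult <- 1 + 3 * spic_amp                    # radius multiplier bound
  halo_mult <- max(1, (1 / r)^(1 / 3)) * 1.15     # edema radial growth bound
  r0_range <- config$tumor_radius_range_mm
  r0 <- stats::runif(1, r0_range[1], r0_range[2])

  fits <- FALSE
  for (attempt in 1:15) {
    ax <- stats::runif(3, 0.8, 1.25)
    ax <- ax / prod(ax)^(1 / 3)
    semi <- r0 * ax / sp                           # semi-axes in voxels
    reach <- max(semi) * max_mult * halo_mult + 2
    lo <- reach
    hi <- shape - 1 - reach
    if (all(hi > lo)) { fits <- TRUE; break }
    r0 <- r0 * 0.8                                 # retry with smaller radius
  }
  if (!fits)
    stop("generate_subject: tumor cannot fit in grid for drawn radius")
  ctr <- stats::runif(3, lo, hi)

  # evaluate the ellipsoid metric only inside the reach bounding box
  bb_lo <- pmax(0L, as.integer(floor(ctr - reach)))
  bb_hi <- pmin(shape - 1L, as.integer(ceiling(ctr + reach)))
  xs <- bb_lo[1]:bb_hi[1]; ys <- bb_lo[2]:bb_hi[2]; zs <- bb_lo[3]:bb_hi[3]
  bb_shape <- c(length(xs), length(ys), length(zs))
  ijk <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dvec <- sweep(ijk, 2, ctr)
  dn <- sqrt(rowSums(dvec^2))
  dirs <- dvec / pmax(dn, 1e-9)
  rho0 <- sqrt(rowSums(sweep(dvec, 2, semi, "/")^2))
  mult <- pmin(pmax(1 + spic_amp * field(dirs), 1 - 2 * spic_amp), max_mult)
  rho <- rho0 / mult

  tumor_in <- rho <= 1
  n_tumor <- sum(tumor_in)
  if (n_tumor < 8)
    stop("generate_subject: degenerate tumor (too few voxels)")
  n_flair <- max(8L, as.integer(round(n_tumor / r)))
  ord <- order(rho)
  if (n_flair > length(ord))
    stop("generate_subject: edema target exceeds evaluated region")
  flair_in <- logical(length(rho))
  flair_in[ord[seq_len(n_flair)]] <- TRUE
  rho_cut <- rho[ord[n_flair]]

  # lift bounding-box logicals onto the full grid
  to_grid <- function(flag) {
    a <- array(0, dim = shape)
    box <- array(as.numeric(flag), dim = bb_shape)
    a[xs + 1, ys + 1, zs + 1] <- box
    a
  }
  tmask <- to_grid(tumor_in)
  fmask <- to_grid(flair_in)
  if (any(tmask[c(1, shape[1]), , ] > 0) || any(tmask[, c(1, shape[2]), ] > 0) ||
      any(tmask[, , c(1, shape[3])] > 0) ||
      any(fmask[c(1, shape[1]), , ] > 0) || any(fmask[, c(1, shape[2]), ] > 0) ||
      any(fmask[, , c(1, shape[3])] > 0))
    stop("generate_subject: mask touches the grid boundary")

  # intensities: enhancing core in ch1 with class-specific texture;
  # edema-like plateau in ch2 with a weak grade-dependent radial component
  t1 <- array(0, dim = shape)
  t1_in_idx <- which(tmask > 0)
  t1[t1_in_idx] <- 1.0 + stats::rnorm(length(t1_in_idx), 0, het)
  fl <- array(0, dim = shape)
  fl_in_idx <- which(fmask > 0)
  fl[fl_in_idx] <- 0.8 + stats::rnorm(length(fl_in_idx), 0, 0.10)
  if (grade == "II" && config$flair_signal_weight > 0) {
    ramp <- pmax(1 - rho / max(rho_cut, 1e-9), 0)
    ramp_grid <- to_grid(ramp * flair_in)
    fl <- fl + config$flair_signal_weight * ramp_grid
  }
  if (config$noise_sd > 0) {
    t1 <- t1 + array(stats::rnorm(prod(shape), 0, config$noise_sd),
                     dim = shape)
    fl <- fl + array(stats::rnorm(prod(shape), 0, config$noise_sd),
                     dim = shape)
  }

  aff <- diag(c(rep(sp, 3), 1))
  location <- sample(names(config$location_probs), 1,
                     prob = config$location_probs)
  list(subject_id = subject_id,
       t1ce = vol3d(t1, spacing = rep(sp, 3), affine = aff, role = "T1CE"),
       flair = vol3d(fl, spacing = rep(sp, 3), affine = aff, role = "FLAIR"),
       t1ce_mask = vol3d(tmask, spacing = rep(sp, 3), affine = aff,
                         role = "MASK"),
       flair_mask = vol3d(fmask, spacing = rep(sp, 3), affine = aff,
                          role = "MASK"),
       grade = grade, location = location,
       r_ratio = n_tumor / n_flair)
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects (grades from `class_probs`, or fixed counts via
#' `grade_counts`), seeded once from `config$seed` so the whole cohort is
#' deterministic. If `out_dir` is given, volumes and masks are written as
#' NIfTI and a CSV manifest
#' (`subject_id,grade,location,r_ratio,t1ce_path,flair_path,t1ce_mask_path,flair_mask_path`)
#' is written alongside; otherwise subjects are returned in memory with the
#' manifest as a data.frame.
#'
#' @param config a [phantom_config()].
#' @param n cohort size (>= 2).
#' @param out_dir optional output directory (created if needed).
#' @param grade_counts optional named vector `c(I = ., II = .)` summing to
#'   `n` for fixed class counts.
#' @param compress write `.nii.gz` (default) rather than `.nii`.
#' @return list with `subjects` (NULL when written to disk to save memory:
#'   always returned in-memory as well here), `manifest` (data.frame), and
#'   `manifest_path` when written.
#' @export
generate_cohort <- function(config, n, out_dir = NULL, grade_counts = NULL,
                            compress = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  n <- as.integer(n)
  if (n < 2L) stop("generate_cohort: n must be >= 2")
  set.seed(config$seed)
  grades <- if (is.null(grade_counts)) {
    sample(c("I", "II"), n, replace = TRUE, prob = config$class_probs)
  } else {
    if (sum(grade_counts) != n)
      stop("generate_cohort: grade_counts must sum to n")
    sample(rep(c("I", "II"), times = grade_counts[c("I", "II")]))
  }
  ids <- sprintf("sub%03d", seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n))
    subjects[[i]] <- generate_subject(config, grades[i], ids[i])

  ext <- if (compress) ".nii.gz" else ".nii"
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok) stop("generate_cohort: cannot create output directory ",
                  out_dir)
  }
  manifest <- data.frame(
    subject_id = ids, grade = grades,
    location = vapply(subjects, function(s) s$location, character(1)),
    r_ratio = vapply(subjects, function(s) s$r_ratio, numeric(1)),
    t1ce_path = paste0(ids, "_t1ce", ext),
    flair_path = paste0(ids, "_flair", ext),
    t1ce_mask_path = paste0(ids, "_t1ce_mask", ext),
    flair_mask_path = paste0(ids, "_flair_mask", ext),
    stringsAsFactors = FALSE)
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      write_volume(s$t1ce, file.path(out_dir, manifest$t1ce_path[i]))
      write_volume(s$flair, file.path(out_dir, manifest$flair_path[i]))
      write_volume(s$t1ce_mask, file.path(out_dir, manifest$t1ce_mask_path[i]))
      write_volume(s$flair_mask,
                   file.path(out_dir, manifest$flair_mask_path[i]))
    }
    manifest_path <- file.path(out_dir, "manifest.csv")
    utils::write.csv(manifest, manifest_path, row.names = FALSE,
                     quote = TRUE)
  }
  list(subjects = subjects, manifest = manifest,
       manifest_path = manifest_path)
}

#' Load a cohort written by [generate_cohort()]
#'
#' @param manifest_path path to `manifest.csv`; volume paths in the manifest
#'   are resolved relative to its directory.
#' @return list with `subjects` and `manifest`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("load_cohort: manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "grade", "location", "r_ratio", "t1ce_path",
            "flair_path", "t1ce_mask_path", "flair_mask_path")
  if (!all(need %in% names(manifest)))
    stop("load_cohort: manifest lacks columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  root <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    list(subject_id = row$subject_id,
         t1ce = read_volume(file.path(root, row$t1ce_path), role = "T1CE"),
         flair = read_volume(file.path(root, row$flair_path),
                             role = "FLAIR"),
         t1ce_mask = read_volume(file.path(root, row$t1ce_mask_path),
                                 role = "MASK"),
         flair_mask = read_volume(file.path(root, row$flair_mask_path),
                                  role = "MASK"),
         grade = row$grade, location = row$location, r_ratio = row$r_ratio)
  })
  list(subjects = subjects, manifest = manifest)
}
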
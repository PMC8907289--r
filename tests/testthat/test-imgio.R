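# Volume container, NIfTI round trips, resampling, volumetry, cropping,
# normalization.

test_that("vol3d enforces geometry and mask invariants", {
  expect_error(vol3d(matrix(0, 2, 2)), "3-D")
  expect_error(vol3d(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  bad_aff <- diag(4); bad_aff[1, 1] <- 0
  expect_error(vol3d(array(0, c(2, 2, 2)), affine = bad_aff), "singular")
  m <- array(0, c(3, 3, 3)); m[2, 2, 2] <- 2
  expect_error(vol3d(m, role = "MASK"), "\\{0, 1\\}")
})

test_that("NIfTI write/read round-trips values and affine", {
  set.seed(10)
  # float32 storage: quantize the fixture through float32 so the round trip
  # is exactly reproducible
  v <- readBin(writeBin(rnorm(512), raw(), size = 4), "double", 512, size = 4)
  aff <- diag(c(1.5, 2, 2.5, 1)); aff[1:3, 4] <- c(-10, 5.25, 3)
  vol <- vol3d(array(v, c(8, 8, 8)), spacing = c(1.5, 2, 2.5), affine = aff)
  for (ext in c(".nii", ".nii.gz")) {
    path <- file.path(tempdir(), paste0("rt", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$values, vol$values)
    expect_equal(back$affine, aff, tolerance = 1e-5)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)
  }
  # masks round-trip bit-exactly through uint8
  mask <- sphere_mask(8, 1, 3)
  mp <- file.path(tempdir(), "mask.nii.gz")
  write_volume(mask, mp)
  expect_identical(read_volume(mp, role = "MASK")$values, mask$values)
})

test_that("NIfTI output matches the nibabel oracle", {
  set.seed(11)
  vol <- vol3d(array(round(rnorm(64), 3), c(4, 4, 4)), spacing = c(1, 2, 3))
  path <- file.path(tempdir(), "oracle.nii.gz")
  write_volume(vol, path)
  py <- file.path(tempdir(), "nib_oracle.py")
  writeLines(c(
    "import sys, nibabel, numpy",
    "img = nibabel.load(sys.argv[1])",
    "d = numpy.asanyarray(img.dataobj).ravel(order='F')",
    "print(' '.join('%.6f' % x for x in d[:5]))",
    "print(' '.join('%.6f' % x for x in img.affine.ravel()))"), py)
  out <- system2("python", c(py, path), stdout = TRUE, stderr = FALSE)
  expect_equal(as.numeric(strsplit(out[1], " ")[[1]]),
               as.vector(vol$values)[1:5], tolerance = 1e-5)
  expect_equal(matrix(as.numeric(strsplit(out[2], " ")[[1]]), 4, 4,
                      byrow = TRUE),
               vol$affine, tolerance = 1e-5)
})

test_that("read_volume rejects malformed and 4-D input", {
  p <- file.path(tempdir(), "bad.nii")
  writeBin(as.raw(1:100), p)
  expect_error(read_volume(p), "NIfTI")
  # craft a 4-D file by patching the dim field of a valid header
  vol <- vol3d(array(0, c(4, 4, 4)))
  p4 <- file.path(tempdir(), "fourd.nii")
  write_volume(vol, p4)
  raw <- readBin(p4, "raw", file.size(p4))
  raw[41:42] <- writeBin(4L, raw(), size = 2)[1:2]  # dim[0] = 4
  raw[49:50] <- writeBin(2L, raw(), size = 2)[1:2]  # dim[4] = 2
  writeBin(raw, p4)
  expect_error(read_volume(p4), "3-D")
})

test_that("resample_to_reference: identity, constants, and mask rules", {
  set.seed(12)
  vol <- vol3d(array(rnorm(1000), c(10, 10, 10)))
  out <- resample_to_reference(vol, vol)
  expect_equal(out$values, vol$values, tolerance = 1e-10)

  cst <- vol3d(array(5, c(8, 8, 8)), spacing = c(2, 2, 2))
  ref <- vol3d(array(0, c(12, 12, 12)))
  res <- resample_to_reference(cst, ref)
  # voxels safely inside the moving FOV keep the constant
  expect_true(all(abs(res$values[2:11, 2:11, 2:11] - 5) < 1e-10))

  mask <- sphere_mask(8, 2, 5)
  expect_error(resample_to_reference(mask, ref, interp = "trilinear"),
               "nearest")
  rm <- resample_to_reference(mask, ref, interp = "nearest")
  expect_true(all(rm$values %in% c(0, 1)))

  far <- vol3d(array(1, c(4, 4, 4)))
  far$affine[1:3, 4] <- c(500, 500, 500)
  expect_warning(resample_to_reference(far, ref), "overlap")
})

test_that("sphere volume survives 2mm -> 1mm resampling within 3%", {
  mask <- sphere_mask(24, 2, 15)
  ref <- vol3d(array(0, c(48, 48, 48)))
  out <- resample_to_reference(mask, ref, interp = "nearest")
  v_analytic <- 4 / 3 * pi * 15^3
  expect_lt(abs(mask_volume_mm3(out) - v_analytic) / v_analytic, 0.03)
})

test_that("resample_isotropic preserves extent and mask volume", {
  set.seed(13)
  vol <- vol3d(array(rnorm(1000), c(10, 10, 10)))
  expect_equal(resample_isotropic(vol, 1)$values, vol$values,
               tolerance = 1e-10)
  v2 <- vol3d(array(rnorm(1000), c(10, 10, 10)), spacing = c(2, 2, 2))
  out <- resample_isotropic(v2, 1)
  expect_equal(dim(out$values), c(20L, 20L, 20L))
  mask <- sphere_mask(24, 2, 14)
  iso <- resample_isotropic(mask, 1, interp = "nearest")
  expect_lt(abs(mask_volume_mm3(iso) - mask_volume_mm3(mask)) /
              mask_volume_mm3(mask), 0.03)
  expect_error(resample_isotropic(vol, -1), "target_mm")
})

test_that("resampling commutes with intensity scaling", {
  set.seed(14)
  vol <- vol3d(array(rnorm(512), c(8, 8, 8)), spacing = c(1.7, 1.7, 1.7))
  ref <- vol3d(array(0, c(12, 12, 12)))
  a <- 3.7
  scaled <- vol; scaled$values <- a * vol$values
  expect_equal(resample_to_reference(scaled, ref)$values,
               a * resample_to_reference(vol, ref)$values, tolerance = 1e-5)
})

test_that("mask_volume_mm3 follows voxel count times voxel volume", {
  m1 <- array(0, c(20, 10, 10)); m1[1:10, 1:10, 1:10] <- 1
  expect_equal(mask_volume_mm3(vol3d(m1, role = "MASK")), 1000)
  expect_equal(mask_volume_mm3(vol3d(array(0, c(5, 5, 5)), role = "MASK")), 0)
  expect_equal(mask_volume_mm3(vol3d(m1, spacing = c(2, 2, 2),
                                     role = "MASK")), 8000)
  img <- vol3d(array(0.5, c(4, 4, 4)))
  expect_error(mask_volume_mm3(img), "MASK")
})

test_that("compute_r_ratio arithmetic and scale invariance", {
  m <- array(0, c(20, 20, 20))
  a <- m; a[1:10, 1:10, 1:10] <- 1               # 1000 voxels
  b <- m; b[seq_len(1250)] <- 1                   # 1250 voxels
  va <- vol3d(a, role = "MASK"); vb <- vol3d(b, role = "MASK")
  expect_equal(compute_r_ratio(va, va), 1.0)
  expect_equal(compute_r_ratio(va, vb), 0.8)
  # scale-free: doubling both spacings leaves R unchanged
  va2 <- vol3d(a, spacing = c(2, 2, 2), role = "MASK")
  vb2 <- vol3d(b, spacing = c(2, 2, 2), role = "MASK")
  expect_equal(compute_r_ratio(va2, vb2), compute_r_ratio(va, vb))
  empty <- vol3d(array(0, c(20, 20, 20)), role = "MASK")
  expect_error(compute_r_ratio(va, empty), "empty FLAIR")
})

test_that("crop_to_roi centres the mask centroid and aligns channels", {
  set.seed(15)
  img <- vol3d(array(rnorm(1000), c(10, 10, 10)))
  full <- vol3d(array(1, c(10, 10, 10)), role = "MASK")
  roi <- crop_to_roi(img, img, full, c(10, 10, 10))
  expect_equal(roi$values[, , , 1], img$values)
  expect_equal(roi$values[, , , 1], roi$values[, , , 2])

  single <- array(0, c(10, 10, 10)); single[6, 6, 6] <- 1  # voxel (5,5,5)
  roi2 <- crop_to_roi(img, img, vol3d(single, role = "MASK"), c(8, 8, 8))
  expect_equal(roi2$crop_origin, c(1L, 1L, 1L))

  # centroid-at-centre property against a brute-force centroid oracle
  for (i in 1:10) {
    m <- array(0, c(16, 16, 16))
    m[sample(16^3, 40)] <- 1
    idx <- which(m == 1, arr.ind = TRUE) - 1
    oracle <- colMeans(idx)
    roi3 <- crop_to_roi(img <- vol3d(array(rnorm(16^3), c(16, 16, 16))),
                        img, vol3d(m, role = "MASK"), c(8, 8, 8))
    centre_src <- roi3$crop_origin + 8 %/% 2
    expect_true(all(abs(centre_src - oracle) <= 1))
  }
  expect_error(crop_to_roi(img, img, vol3d(array(0, c(16, 16, 16)),
                                           role = "MASK"), 8), "empty")
})

test_that("normalize_intensity standardizes the support and is idempotent", {
  cst <- vol3d(array(7, c(6, 6, 6)))
  expect_true(all(normalize_intensity(cst)$values == 0))
  set.seed(16)
  v <- array(0, c(10, 10, 10))
  v[3:8, 3:8, 3:8] <- rnorm(216, mean = 50, sd = 9)
  vol <- vol3d(v)
  n1 <- normalize_intensity(vol)
  sup <- v != 0
  expect_lt(abs(mean(n1$values[sup])), 1e-6)
  expect_lt(abs(stats::sd(n1$values[sup]) - 1), 1e-6)
  # idempotence on an explicit support mask
  mask <- vol3d(array(as.numeric(sup), dim = dim(v)), role = "MASK")
  m1 <- normalize_intensity(vol, mask)
  m2 <- normalize_intensity(m1, mask)
  expect_equal(m2$values, m1$values, tolerance = 1e-10)
})
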
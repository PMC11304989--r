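test_that("resampling produces the expected grid and preserves constants", {
  vol <- ct_volume(array(7, c(100, 100, 100)), spacing = c(1, 1, 1))
  out <- resample_volume(vol, c(2, 0.625, 0.625))
  expect_equal(dim(out$data), c(50L, 160L, 160L))
  expect_true(all(abs(out$data - 7) < 1e-12))
  expect_equal(out$spacing, c(2, 0.625, 0.625))
  expect_equal(out$origin, vol$origin)
})

test_that("resampling at the native spacing reproduces lattice values", {
  set.seed(2)
  vol <- ct_volume(array(rnorm(8 * 10 * 12), c(8, 10, 12)),
                   spacing = c(2, 0.625, 0.625))
  out <- resample_volume(vol, c(2, 0.625, 0.625))
  expect_equal(out$data, vol$data, tolerance = 1e-12)
  expect_error(resample_volume(vol, c(0, 1, 1)), "positive")
})

test_that("intensity normalization maps the window to [-1, 1]", {
  vol <- ct_volume(array(c(-1000, -300, 400, 1000, -2000, 50, 0, -650),
                         c(2, 2, 2)))
  out <- normalize_intensity(vol, c(-1000, 400))
  expect_equal(out$data[1, 1, 1], -1)
  expect_equal(out$data[2, 1, 1], 0)     # window midpoint
  expect_equal(out$data[1, 2, 1], 1)
  expect_equal(out$data[2, 2, 1], 1)     # clipped from above
  expect_equal(out$data[1, 1, 2], -1)    # clipped from below
  # monotone
  v <- sort(runif(50, -1500, 800))
  nv <- normalize_intensity(ct_volume(array(v, c(1, 1, 50))))$data
  expect_true(all(diff(as.vector(nv)) >= 0))
})

test_that("ROI extraction yields 15 x 48 x 48 patches at the default config", {
  expect_equal(roi_dims(preprocess_config()), c(15L, 48L, 48L))
  set.seed(3)
  vol <- ct_volume(array(runif(40 * 120 * 120, -1, 1), c(40, 120, 120)),
                   spacing = c(2, 0.625, 0.625))
  roi <- extract_roi(vol, center_world = c(30, 30, 40), roi_size_mm = 30)
  expect_equal(dim(roi), c(15L, 48L, 48L))
  roi2 <- extract_roi(vol, center_world = c(30, 30, 40), roi_size_mm = 30)
  expect_identical(unclass(roi), unclass(roi2))
})

test_that("out-of-volume ROI regions are padded with -1", {
  vol <- ct_volume(array(0.5, c(20, 60, 60)), spacing = c(2, 0.625, 0.625))
  roi <- extract_roi(vol, c(0, 0, 0), roi_size_mm = 30)
  expect_true(any(roi == -1))
  expect_true(all(roi %in% c(-1, 0.5)))
  expect_error(extract_roi(vol, c(-500, 0, 0), 30), "placement")
})

test_that("ROI extraction commutes with integer-voxel translation", {
  set.seed(4)
  arr <- array(runif(24 * 64 * 64, -1, 1), c(24, 64, 64))
  vol <- ct_volume(arr, spacing = c(2, 0.625, 0.625))
  shift_vox <- c(2L, 4L, -4L)  # (z, y, x); both ROIs stay in valid data
  shifted <- array(-1, dim(arr))
  shifted[(1 + 2):24, (1 + 4):64, 1:(64 - 4)] <-
    arr[1:(24 - 2), 1:(64 - 4), (1 + 4):64]
  vol_s <- ct_volume(shifted, spacing = vol$spacing)
  ctr <- c(20, 18, 22)  # (x, y, z) mm, interior
  # world shift in (x, y, z) order
  ctr_shifted <- ctr + c(shift_vox[3] * vol$spacing[3],
                         shift_vox[2] * vol$spacing[2],
                         shift_vox[1] * vol$spacing[1])
  r1 <- extract_roi(vol, ctr, 15)
  r2 <- extract_roi(vol_s, ctr_shifted, 15)
  expect_equal(unclass(r2), unclass(r1), ignore_attr = TRUE)
})

test_that("negative sampling avoids truth ROIs and is reproducible", {
  lay <- with_seed_layout(seed = 61, density = 100)
  scan <- generate_phantom_scan(lay)
  truth <- scan$annotations
  neg <- sample_negatives(scan$volume, truth, n = 500, seed = 9,
                          roi_size_mm = 30)
  expect_equal(nrow(neg), 500L)
  expect_true(all(neg$label == "negative"))
  neg2 <- sample_negatives(scan$volume, truth, n = 500, seed = 9,
                           roi_size_mm = 30)
  expect_identical(neg, neg2)
  # non-overlap: closest point of each ROI box to the truth centre lies
  # outside the bounding sphere
  half <- 15
  dx <- pmax(abs(neg$coordX - truth$coordX) - half, 0)
  dy <- pmax(abs(neg$coordY - truth$coordY) - half, 0)
  dz <- pmax(abs(neg$coordZ - truth$coordZ) - half, 0)
  expect_true(all(dx^2 + dy^2 + dz^2 > (truth$diameter_mm / 2)^2))
})

test_that("negative sampling on a nodule-free scan fills the budget", {
  lay <- scan_layout("free", NULL, grid_dim = c(30, 48, 48),
                     spacing = c(3, 2.5, 2.5), noise_hu = 10, seed = 3)
  scan <- generate_phantom_scan(lay)
  neg <- sample_negatives(scan$volume, scan$annotations, n = 1000, seed = 1)
  expect_equal(nrow(neg), 1000L)
})

test_that("positive oversampling multiplies positives and conserves counts", {
  rois <- tibble::tibble(
    id = 1:12,
    label = factor(rep(c("positive", "negative"), c(2, 10)),
                   levels = c("negative", "positive", "unknown"))
  )
  out <- oversample_positives(rois, factor = 250, seed = 2)
  expect_equal(sum(out$label == "positive"), 2L * 250L)
  expect_equal(sum(out$label == "negative"), 10L)
  # factor 1 is the identity up to ordering
  out1 <- oversample_positives(rois, factor = 1, seed = 2)
  expect_equal(sort(out1$id), rois$id)
  expect_error(oversample_positives(rois, factor = 0.5))
})

test_that("scan filtering drops thick, irregular and gappy stacks", {
  meta <- tibble::tibble(
    seriesuid = c("thick", "gap", "irregular", "good"),
    slice_thickness_mm = c(3, 2, 2, 2),
    z_positions = list(
      seq(0, 40, by = 3),
      c(seq(0, 10, by = 2), seq(14, 24, by = 2)),  # one missing slice
      c(0, 2, 4.01, 6, 8),
      seq(0, 20, by = 2)
    )
  )
  kept <- filter_scans(meta)
  expect_equal(kept$seriesuid, "good")
  # boundary: exactly 2.5 mm is kept
  meta2 <- tibble::tibble(seriesuid = "edge", slice_thickness_mm = 2.5,
                          z_positions = list(seq(0, 25, by = 2.5)))
  expect_equal(nrow(filter_scans(meta2)), 1L)
})

test_that("the full-scale sampling bookkeeping matches S x N", {
  # S scans at N negatives per scan yield exactly S * N negatives
  S <- 3; N <- 40
  lay <- phantom_layouts(n_scans = S, grid_dim = c(24, 40, 40),
                         spacing = c(3, 2.5, 2.5), nodules_per_scan = 1,
                         seed = 5)
  total <- 0L
  for (l in lay) {
    scan <- generate_phantom_scan(l)
    total <- total + nrow(sample_negatives(scan$volume, scan$annotations,
                                           n = N, seed = l$seed,
                                           roi_size_mm = 24))
  }
  expect_equal(total, S * N)
})
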
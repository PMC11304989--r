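spc <- c(2, 0.625, 0.625)



test_that("spherical masks match the analytic ball volume", {
  for (d in c(5, 8, 10, 20)) {
    m <- generate_nodule_mask("spherical", d, spc)
    vox_vol <- sum(m) * prod(spc)
    expect_lt(abs(vox_vol - 4 / 3 * pi * (d / 2)^3) / (4 / 3 * pi * (d / 2)^3),
              0.15)
  }
})

test_that("spherical masks are invariant under axis flips", {
  m <- generate_nodule_mask("spherical", 8, spc)
  for (ax in 1:3) {
    flipped <- switch(ax,
      m[rev(seq_len(dim(m)[1])), , ],
      m[, rev(seq_len(dim(m)[2])), ],
      m[, , rev(seq_len(dim(m)[3]))]
    )
    expect_identical(as.vector(flipped), as.vector(m))
  }
})

test_that("spiculated masks strictly exceed their central sphere", {
  for (seed in 1:5) {
    m <- generate_nodule_mask("spiculated", 10, spc, seed = seed)
    # brute-force voxel count of the bare core sphere on the same grid
    dims <- dim(m)
    g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                     x = seq_len(dims[3]))
    ctr <- attr(m, "center_index") + 1
    r2 <- ((g$z - ctr[1]) * spc[1])^2 + ((g$y - ctr[2]) * spc[2])^2 +
      ((g$x - ctr[3]) * spc[3])^2
    core_count <- sum(r2 <= (0.35 * 10)^2)
    expect_gt(sum(m), core_count)
  }
})

test_that("all shape families stay inside the 1.5 d bounding box and are seeded", {
  for (fam in c("spherical", "elliptical", "lobulated", "spiculated")) {
    m1 <- generate_nodule_mask(fam, 10, spc, seed = 3)
    m2 <- generate_nodule_mask(fam, 10, spc, seed = 3)
    expect_identical(m1, m2)
    ext <- dim(m1) * spc
    expect_true(all(ext <= 1.5 * 10 + 2 * spc))
    expect_gt(sum(m1), 0)
  }
})

test_that("sub-voxel diameters raise a degenerate-shape error", {
  expect_error(generate_nodule_mask("spherical", 1.5, spc), "degenerate")
})

test_that("a nodule-free phantom scan contains only the background materials", {
  lay <- scan_layout("p0", NULL, grid_dim = c(24, 40, 40),
                     spacing = c(3, 2.5, 2.5), noise_hu = 10, seed = 5)
  scan <- generate_phantom_scan(lay)
  expect_equal(nrow(scan$annotations), 0L)
  mats <- c(-1000, -850, 40, 50)
  dist_to_mat <- apply(abs(outer(as.vector(scan$volume$data), mats, "-")),
                       1, min)
  # max |N(0, 10)| over ~4e4 voxels concentrates near 4.1 sigma; allow 5
  expect_lt(max(dist_to_mat), 5 * 10)
})

test_that("inserted nodules hit their target density at the core", {
  lay <- with_seed_layout(seed = 9, density = 100)
  scan <- generate_phantom_scan(lay)
  ann <- scan$annotations
  idx <- world_to_voxel(scan$volume,
                        c(ann$coordX, ann$coordY, ann$coordZ))
  ctr <- round(idx) + 1
  # central slice, +/- 1 in-plane voxel: all well inside the 6 mm radius
  core <- scan$volume$data[ctr[1],
                           (ctr[2] - 1):(ctr[2] + 1),
                           (ctr[3] - 1):(ctr[3] + 1)]
  expect_lt(abs(mean(core) - 100), 40)
})

test_that("phantom scans are bit-identical for a fixed layout seed", {
  lay <- with_seed_layout(seed = 21, density = -10)
  s1 <- generate_phantom_scan(lay)
  s2 <- generate_phantom_scan(lay)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$annotations, s2$annotations)
})

test_that("overlapping nodules raise a layout error", {
  grid_dim <- c(40, 64, 64)
  spacing <- c(3, 1.875, 1.875)
  ext <- grid_dim * spacing
  p <- c(0.29 * ext[3], 0.48 * ext[2], 0.5 * ext[1])
  nods <- tibble::tibble(
    shape = "spherical", diameter_mm = c(10, 10),
    density_hu = c(100, 100),
    x = c(p[1], p[1] + 2), y = c(p[2], p[2]), z = c(p[3], p[3])
  )
  lay <- scan_layout("ovl", nods, grid_dim = grid_dim, spacing = spacing,
                     noise_hu = 0, seed = 1)
  expect_error(generate_phantom_scan(lay), "overlap")
})

test_that("clinical difficulty adds mimic structures beyond the phantom", {
  # count bright connected structures (above -500 HU) inside the lung zone
  bright_lung_components <- function(vol) {
    geom <- nodulefpr:::thorax_geometry(dim(vol$data), vol$spacing)
    g <- nodulefpr:::coord_grids(dim(vol$data), vol$spacing,
                                 center_index = c(0, 0, 0))
    pts <- cbind(as.vector(g$z), as.vector(g$y), as.vector(g$x))
    lung <- array(nodulefpr:::lung_radius2(pts, geom) <= 1, dim(vol$data))
    count_components(vol$data > -500 & lung)
  }
  clin <- generate_clinical_scan(seed = 31, difficulty = 1, n_nodules = 2,
                                 grid_dim = c(24, 48, 48),
                                 spacing = c(3, 2, 2), noise_hu = 5)
  phan_layout <- scan_layout("p", nodulefpr:::with_seed(31, {
    nodulefpr:::draw_nodules(2, c(24, 48, 48), c(3, 2, 2), difficulty = 0)
  }), grid_dim = c(24, 48, 48), spacing = c(3, 2, 2), noise_hu = 5,
  seed = 31)
  phan <- generate_phantom_scan(phan_layout)
  expect_gt(bright_lung_components(clin$volume),
            bright_lung_components(phan$volume))
})

test_that("clinical difficulty zero stays close to phantom statistics", {
  clin0 <- generate_clinical_scan(seed = 41, difficulty = 0, n_nodules = 2,
                                  grid_dim = c(24, 48, 48),
                                  spacing = c(3, 2, 2), noise_hu = 5)
  expect_equal(nrow(clin0$annotations), 2L)
  # at difficulty 0 sizes and densities come from the phantom catalogue
  expect_true(all(clin0$annotations$diameter_mm %in% c(5, 8, 10, 20)))
})

test_that("seeded clinical scans reproduce and honour the nodule count", {
  a <- generate_clinical_scan(seed = 17, difficulty = 0.5, n_nodules = 3,
                              grid_dim = c(24, 48, 48), spacing = c(3, 2, 2))
  b <- generate_clinical_scan(seed = 17, difficulty = 0.5, n_nodules = 3,
                              grid_dim = c(24, 48, 48), spacing = c(3, 2, 2))
  expect_identical(a$volume$data, b$volume$data)
  expect_equal(nrow(a$annotations), 3L)
})

test_that("candidate proposal recalls truths and fills the budget", {
  lay <- with_seed_layout(seed = 51, density = 100)
  scan <- generate_phantom_scan(lay)
  cand <- propose_candidates(scan$volume, scan$annotations,
                             n_per_scan = 750, sensitivity = 1, seed = 2)
  expect_equal(nrow(cand), 750L)
  expect_gte(sum(cand$label == "positive"), 1L)
  # jitter is within a quarter diameter: recalled truth candidate is a hit
  d <- sqrt((cand$coordX - scan$annotations$coordX)^2 +
              (cand$coordY - scan$annotations$coordY)^2 +
              (cand$coordZ - scan$annotations$coordZ)^2)
  expect_lte(min(d), 0.25 * scan$annotations$diameter_mm)

  none <- propose_candidates(scan$volume, scan$annotations,
                             n_per_scan = 100, sensitivity = 0, seed = 2)
  expect_true(all(none$label == "negative"))
})

test_that("a radius-spread statistic separates spherical from spiculated", {
  # sanity floor for learnability: a trivial shape feature must separate
  # the extreme families on 100 seeded draws
  spread <- function(m) {
    spc <- attr(m, "spacing")
    d <- dim(m)
    ctr <- attr(m, "center_index") + 1
    idx <- which(m)
    ai <- arrayInd(idx, d)
    r <- sqrt(((ai[, 1] - ctr[1]) * spc[1])^2 +
                ((ai[, 2] - ctr[2]) * spc[2])^2 +
                ((ai[, 3] - ctr[3]) * spc[3])^2)
    stats::sd(r) / mean(r)
  }
  stats <- vapply(1:100, function(s) {
    fam <- if (s %% 2 == 0) "spherical" else "spiculated"
    c(is_spic = as.numeric(s %% 2 == 1),
      stat = spread(generate_nodule_mask(fam, 10, c(2, 0.625, 0.625),
                                         seed = s)))
  }, numeric(2))
  thr <- stats::median(stats["stat", ])
  acc <- mean((stats["stat", ] > thr) == (stats["is_spic", ] == 1))
  expect_gt(acc, 0.9)
})

test_that("simulate_dataset writes volumes, annotations and a manifest", {
  dir <- withr::local_tempdir()
  mf <- simulate_dataset("phantom", n_scans = 2, dir = dir, seed = 3,
                         grid_dim = c(16, 32, 32), spacing = c(4, 3, 3),
                         nodules_per_scan = 1)
  expect_equal(nrow(mf), 2L)
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  vol <- read_volume(file.path(dir, "phantom_0001.mhd"))
  expect_equal(dim(vol$data), c(16L, 32L, 32L))
})
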
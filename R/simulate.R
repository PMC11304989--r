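#' Synthetic nodule shape masks
#'
#' Generates a voxel occupancy mask for one synthetic pulmonary nodule of a
#' given shape family, mirroring the inventory of an anthropomorphic thorax
#' phantom: `spherical` (a ball of diameter `diameter_mm`), `elliptical`
#' (an ellipsoid with axis ratios drawn from `[0.6, 1]`, rescaled so the mean
#' axis equals the nominal diameter), `lobulated` (a union of 3--6
#' overlapping spheres with radii in `[0.3, 0.5] * d`), and `spiculated`
#' (a central sphere of radius `0.35 d` with 8--16 tapering radial spikes).
#' All shapes fit a bounding box of at most `1.5 * diameter_mm` per axis.
#'
#' @param shape_family One of `"spherical"`, `"elliptical"`, `"lobulated"`,
#'   `"spiculated"`.
#' @param diameter_mm Nominal nodule diameter in mm; must exceed the voxel
#'   size along every axis.
#' @param spacing Voxel spacing `(z, y, x)` in mm.
#' @param seed Optional integer; when given, the stochastic families
#'   (elliptical, lobulated, spiculated) are reproducible. `NULL` draws from
#'   the current RNG stream.
#' @return A logical 3D array (odd dimensions, nodule centred) with
#'   attributes `spacing` and `center_index` (0-based voxel index of the
#'   nodule centre).
#' @export
#' @examples
#' m <- generate_nodule_mask("spherical", 5, c(2, 0.625, 0.625))
#' sum(m) * prod(attr(m, "spacing"))   # approximately (4/3) * pi * 2.5^3
generate_nodule_mask <- function(shape_family, diameter_mm, spacing,
                                 seed = NULL) {
  shape_family <- match.arg(shape_family, nodule_shape_families())
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive", call. = FALSE)
  if (any(diameter_mm < spacing)) {
    stop("degenerate shape: diameter ", diameter_mm,
         " mm is smaller than one voxel along axis ",
         which(diameter_mm < spacing)[1], call. = FALSE)
  }
  with_seed(seed, {
    d <- diameter_mm
    half <- pmax(1L, floor((0.75 * d) / spacing))
    dims <- 2L * half + 1L
    g <- coord_grids(dims, spacing)
    occ <- switch(shape_family,
      spherical = g$z^2 + g$y^2 + g$x^2 <= (d / 2)^2,
      elliptical = {
        s <- stats::runif(3, 0.6, 1.0)
        s <- s / mean(s)
        a <- s * d / 2
        (g$z / a[1])^2 + (g$y / a[2])^2 + (g$x / a[3])^2 <= 1
      },
      lobulated = {
        k <- sample(3:6, 1)
        occ <- array(FALSE, dims)
        for (i in seq_len(k)) {
          r <- stats::runif(1, 0.3, 0.5) * d
          off <- random_unit_vector() *
            stats::runif(1, 0, min(0.3 * d, 0.75 * d - r))
          occ <- occ |
            ((g$z - off[1])^2 + (g$y - off[2])^2 + (g$x - off[3])^2 <= r^2)
        }
        occ
      },
      spiculated = {
        core_r <- 0.35 * d
        occ <- g$z^2 + g$y^2 + g$x^2 <= core_r^2
        n_spikes <- sample(8:16, 1)
        r2 <- sqrt(g$z^2 + g$y^2 + g$x^2)
        for (i in seq_len(n_spikes)) {
          u <- random_unit_vector()
          l_tot <- core_r + stats::runif(1, 0.1, 0.4) * d
          t <- g$z * u[1] + g$y * u[2] + g$x * u[3]
          perp2 <- pmax(r2^2 - t^2, 0)
          w <- 0.14 * d * pmax(1 - t / l_tot, 0)
          occ <- occ | (t > 0 & t <= l_tot & perp2 <= w^2)
        }
        occ
      }
    )
    structure(occ, spacing = spacing, center_index = as.numeric(half))
  })
}

nodule_shape_families <- function() {
  c("spherical", "elliptical", "lobulated", "spiculated")
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Phantom nodule inventory
#'
#' The default 48-nodule catalogue: 4 shape families x 4 diameters
#' (5, 8, 10, 20 mm) x 3 densities (-630, -10, 100 HU), matching the
#' insertable-nodule inventory of an anthropomorphic thoracic phantom.
#'
#' @return A tibble with columns `shape`, `diameter_mm`, `density_hu` and
#'   `shape_seed`. The seed fixes the shape realization: like the physical
#'   inventory, the same 48 manufactured nodules recur across scans rather
#'   than a fresh random shape being drawn per placement.
#' @export
phantom_catalogue <- function() {
  out <- tidyr::expand_grid(
    shape = nodule_shape_families(),
    diameter_mm = c(5, 8, 10, 20),
    density_hu = c(-630, -10, 100)
  )
  out$shape_seed <- seq_len(nrow(out))
  out
}

#' Scan layout: nodules plus acquisition protocol
#'
#' A `scan_layout` pins down everything [generate_phantom_scan()] needs:
#' the grid geometry, the noise level standing in for dose/kernel variation,
#' a seed, and one row per nodule with its shape, size, density and world
#' position.
#'
#' @param scan_id Character scan identifier.
#' @param nodules A tibble with columns `shape`, `diameter_mm`, `density_hu`,
#'   `x`, `y`, `z` (world mm) and optionally `attachment`
#'   (`none`/`vessel`/`pleural`). May have zero rows.
#' @param grid_dim Grid dimensions `(nz, ny, nx)`.
#' @param spacing Voxel spacing `(z, y, x)` mm.
#' @param noise_hu Additive Gaussian noise standard deviation in HU.
#' @param seed Integer seed making the rendered scan reproducible.
#' @return An object of class `scan_layout`.
#' @export
scan_layout <- function(scan_id, nodules = NULL,
                        grid_dim = c(40, 64, 64),
                        spacing = c(3, 1.875, 1.875),
                        noise_hu = 12, seed = 1L) {
  if (is.null(nodules)) {
    nodules <- tibble::tibble(
      shape = character(), diameter_mm = numeric(), density_hu = numeric(),
      x = numeric(), y = numeric(), z = numeric(), attachment = character()
    )
  }
  if (!"attachment" %in% names(nodules)) {
    nodules$attachment <- rep("none", nrow(nodules))
  }
  stopifnot(all(c("shape", "diameter_mm", "density_hu", "x", "y", "z")
                %in% names(nodules)))
  if (nrow(nodules) > 0 && any(nodules$diameter_mm <= 0)) {
    stop("nodule diameters must be positive", call. = FALSE)
  }
  structure(
    list(scan_id = as.character(scan_id), nodules = tibble::as_tibble(nodules),
         grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
         noise_hu = noise_hu, seed = as.integer(seed)),
    class = "scan_layout"
  )
}

#' @export
print.scan_layout <- function(x, ...) {
  cat(sprintf("<scan_layout> %s: %d nodule(s), grid %s @ %s mm, noise %g HU\n",
              x$scan_id, nrow(x$nodules),
              paste(x$grid_dim, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$noise_hu))
  invisible(x)
}

# Simplified thorax geometry shared by the renderer and the samplers: an
# elliptic body cylinder with a soft-tissue wall, two ellipsoidal lungs and
# per-lung vessel entry points. All in world mm (origin at voxel (0,0,0)).
thorax_geometry <- function(grid_dim, spacing) {
  ext <- grid_dim * spacing  # (z, y, x)
  list(
    ext = ext,
    body_center = c(0.5 * ext[2], 0.5 * ext[3]),       # (y, x)
    body_semi = c(0.42 * ext[2], 0.46 * ext[3]),
    wall_mm = 6,
    lung_centers = rbind(
      c(0.5 * ext[1], 0.48 * ext[2], 0.29 * ext[3]),   # (z, y, x) left
      c(0.5 * ext[1], 0.48 * ext[2], 0.71 * ext[3])    # right
    ),
    lung_semi = c(0.44 * ext[1], 0.27 * ext[2], 0.165 * ext[3])
  )
}

# Normalized squared lung radius of world points (n x 3 matrix, (z,y,x)):
# the minimum over the two lungs; <= 1 means inside a lung.
lung_radius2 <- function(pts, geom) {
  r2 <- rep(Inf, nrow(pts))
  for (l in 1:2) {
    c0 <- geom$lung_centers[l, ]
    r2 <- pmin(r2,
      ((pts[, 1] - c0[1]) / geom$lung_semi[1])^2 +
      ((pts[, 2] - c0[2]) / geom$lung_semi[2])^2 +
      ((pts[, 3] - c0[3]) / geom$lung_semi[3])^2)
  }
  r2
}

#' Generate a phantom-like CT scan
#'
#' Renders a simplified anthropomorphic thorax: air (-1000 HU) around an
#' elliptic body with a soft-tissue chest wall (+40 HU), two ellipsoidal
#' lungs of foam-like parenchyma (-850 HU), a branching tubular vascular
#' insert (+50 HU), and the layout's synthetic nodules at their specified
#' densities with Gaussian edge smoothing emulating partial-volume blur.
#' Additive Gaussian noise at the protocol level is applied last. The output
#' is a pure function of the layout (including its seed).
#'
#' @param layout A [scan_layout()].
#' @return A list with elements `volume` (a [ct_volume()] in HU) and
#'   `annotations` (tibble: `seriesuid`, `coordX`, `coordY`, `coordZ`,
#'   `diameter_mm`, `agreement` = 4), one row per nodule.
#' @export
generate_phantom_scan <- function(layout) {
  stopifnot(inherits(layout, "scan_layout"))
  render_scan(layout, clinical = FALSE, difficulty = 0)
}

#' Generate a clinical-like CT scan
#'
#' Same thorax model as [generate_phantom_scan()] plus the structures that
#' make clinical false-positive reduction hard: denser bifurcating vessel
#' trees, dark airway tubes with soft walls, textured parenchyma,
#' scar-like bright blobs (hard mimics, absent from the ground truth),
#' pleural-attached nodules and occasional calcified nodules (up to
#' +400 HU). The `difficulty` knob in `[0, 1]` scales all of these; at 0 the
#' scan is distributionally close to phantom mode.
#'
#' @param seed Integer seed; the scan is a pure function of the arguments.
#' @param difficulty Mimic richness in `[0, 1]`.
#' @param n_nodules Number of true nodules; default draws 2--5.
#' @param grid_dim,spacing,noise_hu As in [scan_layout()].
#' @param scan_id Scan identifier.
#' @return As [generate_phantom_scan()].
#' @export
generate_clinical_scan <- function(seed, difficulty = 1, n_nodules = NULL,
                                   grid_dim = c(40, 64, 64),
                                   spacing = c(3, 1.875, 1.875),
                                   noise_hu = 12,
                                   scan_id = paste0("clinical_", seed)) {
  stopifnot(difficulty >= 0, difficulty <= 1)
  layout <- with_seed(child_seed(seed, 101L), {
    n <- if (is.null(n_nodules)) sample(2:5, 1) else n_nodules
    nods <- draw_nodules(n, grid_dim, spacing, difficulty)
    scan_layout(scan_id, nods, grid_dim = grid_dim, spacing = spacing,
                noise_hu = noise_hu, seed = child_seed(seed, 202L))
  })
  render_scan(layout, clinical = TRUE, difficulty = difficulty)
}

# Draw nodule specs with positions inside the lungs; clinical mode widens
# the density distribution and allows pleural attachment.
draw_nodules <- function(n, grid_dim, spacing, difficulty = 0,
                         catalogue = phantom_catalogue()) {
  geom <- thorax_geometry(grid_dim, spacing)
  rows <- catalogue[sample.int(nrow(catalogue), n, replace = TRUE), ]
  out <- rows
  out$attachment <- "none"
  if (!"shape_seed" %in% names(out)) out$shape_seed <- NA_integer_
  if (difficulty > 0) {
    widen <- stats::runif(n) < difficulty
    out$density_hu[widen] <- stats::runif(sum(widen), -650, 120)
    calc <- stats::runif(n) < 0.15 * difficulty
    out$density_hu[calc] <- stats::runif(sum(calc), 200, 400)
    pleural <- stats::runif(n) < 0.25 * difficulty
    out$attachment[pleural] <- "pleural"
    # clinical nodules are individually shaped, not a recurring inventory
    out$shape_seed[stats::runif(n) < difficulty] <- NA_integer_
  }
  pos <- place_nodules(out$diameter_mm, out$attachment, geom)
  out$z <- pos[, 1]; out$y <- pos[, 2]; out$x <- pos[, 3]
  tibble::as_tibble(out)
}

place_nodules <- function(diameters, attachment, geom, max_tries = 400L,
                          restarts = 25L) {
  # greedy placement can dead-end when early nodules block the lung; on
  # failure the whole configuration is redrawn
  for (r in seq_len(restarts)) {
    pos <- try(place_nodules_once(diameters, attachment, geom, max_tries),
               silent = TRUE)
    if (!inherits(pos, "try-error")) return(pos)
  }
  stop("could not place ", length(diameters),
       " nodules without overlap after ", restarts, " restarts",
       call. = FALSE)
}

place_nodules_once <- function(diameters, attachment, geom, max_tries) {
  n <- length(diameters)
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    target_r <- if (attachment[i] == "pleural") c(0.85, 0.98) else c(0, 0.7)
    for (try in seq_len(max_tries)) {
      lung <- sample(1:2, 1)
      u <- random_unit_vector()
      # interior nodules: uniform over the lung ellipsoid core; pleural:
      # a thin shell near the lung surface
      rad <- if (attachment[i] == "pleural") {
        stats::runif(1, target_r[1], target_r[2])
      } else {
        target_r[2] * stats::runif(1)^(1 / 3)
      }
      p <- geom$lung_centers[lung, ] + u * rad * geom$lung_semi
      ok <- TRUE
      if (i > 1) {
        prev <- pos[seq_len(i - 1), , drop = FALSE]
        dd <- sqrt(rowSums(sweep(prev, 2, p)^2))
        ok <- all(dd > (diameters[seq_len(i - 1)] + diameters[i]) / 2 + 4)
      }
      if (ok) { pos[i, ] <- p; break }
    }
    if (anyNA(pos[i, ])) {
      stop("could not place nodule ", i, " without overlap", call. = FALSE)
    }
  }
  pos
}

# Shared renderer for phantom and clinical modes.
render_scan <- function(layout, clinical, difficulty) {
  with_seed(layout$seed, {
    dims <- layout$grid_dim
    sp <- layout$spacing
    geom <- thorax_geometry(dims, sp)
    g <- coord_grids(dims, sp, center_index = c(0, 0, 0))
    # world coords of voxel centres (origin at voxel 0,0,0)
    ey <- (g$y - geom$body_center[1]) / geom$body_semi[1]
    ex <- (g$x - geom$body_center[2]) / geom$body_semi[2]
    body <- ey^2 + ex^2 <= 1
    hu <- array(-1000, dims)
    hu[body] <- 40
    pts <- cbind(as.vector(g$z), as.vector(g$y), as.vector(g$x))
    lung <- array(lung_radius2(pts, geom) <= 1, dims)
    hu[lung] <- -850

    if (clinical && difficulty > 0) {
      tex <- smooth_noise_field(dims, c(0.8, 1.2, 1.2)) * 35 * difficulty
      hu[lung] <- hu[lung] + tex[lung]
    }

    # vascular insert: one branching tree per lung
    n_extra <- if (clinical) round(difficulty * 2) else 0
    for (l in 1:2) {
      for (tree in seq_len(1 + n_extra)) {
        segs <- vessel_tree(geom, lung = l,
                            depth = if (clinical) 4L else 3L)
        hu <- render_tubes(hu, segs, value = 50, dims, sp, lung_only = lung)
      }
      if (clinical && difficulty > 0 && stats::runif(1) < difficulty) {
        segs <- vessel_tree(geom, lung = l, depth = 3L, radius0 = 2.2)
        hu <- render_tubes(hu, segs, value = -1000, dims, sp,
                           lung_only = lung, wall_value = -200,
                           wall_mm = 1.5)
      }
    }

    # scar-like hard mimics (clinical only; never annotated)
    if (clinical && difficulty > 0) {
      n_mimic <- stats::rpois(1, 3 * difficulty)
      for (m in seq_len(n_mimic)) {
        d_m <- stats::runif(1, 4, 9)
        p_m <- place_nodules(d_m, "none", geom)
        dens <- stats::runif(1, -250, 60)
        hu <- blend_nodule(hu, "lobulated", d_m, dens, p_m[1, ], dims, sp)$hu
      }
    }

    # true nodules
    occupied <- NULL
    ann <- layout$nodules
    if (nrow(ann) > 0) {
      shape_seeds <- if ("shape_seed" %in% names(ann)) ann$shape_seed else
        rep(NA_integer_, nrow(ann))
      for (i in seq_len(nrow(ann))) {
        res <- blend_nodule(hu, ann$shape[i], ann$diameter_mm[i],
                            ann$density_hu[i], c(ann$z[i], ann$y[i], ann$x[i]),
                            dims, sp, occupied = occupied,
                            shape_seed = shape_seeds[i])
        hu <- res$hu
        occupied <- res$occupied
      }
    }

    if (layout$noise_hu > 0) {
      hu <- hu + stats::rnorm(length(hu), sd = layout$noise_hu)
    }

    vol <- ct_volume(hu, spacing = sp, origin = c(0, 0, 0))
    annotations <- tibble::tibble(
      seriesuid = rep(layout$scan_id, nrow(ann)),
      coordX = ann$x, coordY = ann$y, coordZ = ann$z,
      diameter_mm = ann$diameter_mm,
      agreement = rep(4L, nrow(ann))
    )
    list(volume = vol, annotations = annotations)
  })
}

# Insert one nodule into `hu` with partial-volume edge smoothing; tracks a
# global occupancy list to reject overlapping layouts.
blend_nodule <- function(hu, shape, diameter_mm, density_hu, center_zyx,
                         dims, spacing, occupied = NULL, shape_seed = NULL) {
  if (!is.null(shape_seed) && is.na(shape_seed)) shape_seed <- NULL
  mask <- generate_nodule_mask(shape, diameter_mm, spacing,
                               seed = shape_seed)
  frac <- gauss_blur3d(mask * 1.0, c(0.6, 0.6, 0.6))
  mdim <- dim(mask)
  c_idx <- attr(mask, "center_index")
  start <- round(center_zyx / spacing) - c_idx + 1  # 1-based array start
  src_lo <- pmax(1 - start + 1, 1)
  src_hi <- pmin(dims - start + 1, mdim)
  if (any(src_lo > src_hi)) return(list(hu = hu, occupied = occupied))
  dst_lo <- start + src_lo - 1
  dst_hi <- start + src_hi - 1
  sub <- frac[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3],
              drop = FALSE]
  solid <- mask[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3],
                drop = FALSE]
  zi <- dst_lo[1]:dst_hi[1]; yi <- dst_lo[2]:dst_hi[2]; xi <- dst_lo[3]:dst_hi[3]
  if (!is.null(occupied)) {
    key <- cbind(
      rep(zi, times = length(yi) * length(xi)),
      rep(rep(yi, each = length(zi)), times = length(xi)),
      rep(xi, each = length(zi) * length(yi))
    )[as.vector(solid), , drop = FALSE]
    if (nrow(key) > 0) {
      hit <- occupied[key]
      if (any(hit)) stop("layout error: overlapping nodules", call. = FALSE)
    }
  }
  occ <- occupied
  if (is.null(occ)) occ <- array(FALSE, dims)
  occ[zi, yi, xi] <- occ[zi, yi, xi] | solid
  hu[zi, yi, xi] <- (1 - sub) * hu[zi, yi, xi] + sub * density_hu
  list(hu = hu, occupied = occ)
}

# Recursive branching tube tree. Returns a matrix of segments
# (z0, y0, x0, z1, y1, x1, radius) in world mm.
vessel_tree <- function(geom, lung, depth = 3L, radius0 = 2.8) {
  start <- geom$lung_centers[lung, ] +
    c(-0.8, 0, if (lung == 1) 0.6 else -0.6) * geom$lung_semi
  dir0 <- c(0.9, stats::runif(1, -0.3, 0.3),
            if (lung == 1) -0.5 else 0.5)
  dir0 <- dir0 / sqrt(sum(dir0^2))
  segs <- list()
  grow <- function(p, dir, radius, level) {
    len <- stats::runif(1, 10, 18) * 0.85^level
    q <- p + dir * len
    segs[[length(segs) + 1L]] <<- c(p, q, radius)
    if (level >= depth) return()
    n_child <- if (stats::runif(1) < 0.75) 2L else 1L
    for (b in seq_len(n_child)) {
      ndir <- dir + stats::rnorm(3, sd = 0.45)
      ndir <- ndir / sqrt(sum(ndir^2))
      grow(q, ndir, radius * 0.72, level + 1L)
    }
  }
  grow(start, dir0, radius0, 0L)
  do.call(rbind, segs)
}

# Paint tube segments into the HU array. `lung_only` restricts painting to
# lung voxels (the vascular insert sits inside the lungs). Optional wall.
render_tubes <- function(hu, segs, value, dims, spacing, lung_only = NULL,
                         wall_value = NULL, wall_mm = 0) {
  for (s in seq_len(nrow(segs))) {
    p0 <- segs[s, 1:3]; p1 <- segs[s, 4:6]; r <- segs[s, 7]
    pad <- r + wall_mm + max(spacing)
    lo <- pmax(floor((pmin(p0, p1) - pad) / spacing) + 1, 1)
    hi <- pmin(ceiling((pmax(p0, p1) + pad) / spacing) + 1, dims)
    if (any(lo > hi)) next
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    bdim <- c(length(zi), length(yi), length(xi))
    gz <- array(rep((zi - 1) * spacing[1], times = bdim[2] * bdim[3]), bdim)
    gy <- array(rep(rep((yi - 1) * spacing[2], each = bdim[1]),
                    times = bdim[3]), bdim)
    gx <- array(rep((xi - 1) * spacing[3], each = bdim[1] * bdim[2]), bdim)
    v <- p1 - p0
    vv <- sum(v^2)
    tz <- gz - p0[1]; ty <- gy - p0[2]; tx <- gx - p0[3]
    t <- clip((tz * v[1] + ty * v[2] + tx * v[3]) / vv, 0, 1)
    d2 <- (tz - t * v[1])^2 + (ty - t * v[2])^2 + (tx - t * v[3])^2
    inside <- d2 <= r^2
    sel_wall <- NULL
    if (!is.null(wall_value) && wall_mm > 0) {
      sel_wall <- d2 > r^2 & d2 <= (r + wall_mm)^2
    }
    region <- hu[zi, yi, xi]
    keep <- if (is.null(lung_only)) TRUE else lung_only[zi, yi, xi]
    paint <- inside & keep
    region[paint] <- value
    if (!is.null(sel_wall)) region[sel_wall & keep] <- wall_value
    hu[zi, yi, xi] <- region
  }
  hu
}

#' Default phantom dataset layouts
#'
#' Builds the layout collection for the phantom training database: `n_scans`
#' scan layouts, each holding nodules drawn from the 48-piece
#' [phantom_catalogue()] placed without overlap inside the lungs.
#'
#' @param n_scans Number of layouts (default 569, the size of the phantom
#'   scan database the pipeline emulates).
#' @param nodules_per_scan Integer vector sampled per scan (default 2--5).
#' @param grid_dim,spacing,noise_hu Passed to [scan_layout()].
#' @param seed Master seed; layout `i` derives a child seed from it.
#' @return A list of [scan_layout()] objects.
#' @export
phantom_layouts <- function(n_scans = 569, nodules_per_scan = 2:5,
                            grid_dim = c(40, 64, 64),
                            spacing = c(3, 1.875, 1.875),
                            noise_hu = 12, seed = 1L) {
  lapply(seq_len(n_scans), function(i) {
    with_seed(child_seed(seed, i), {
      n <- if (length(nodules_per_scan) == 1L) nodules_per_scan
           else sample(nodules_per_scan, 1)
      nods <- draw_nodules(n, grid_dim, spacing, difficulty = 0)
      scan_layout(sprintf("phantom_%04d", i), nods, grid_dim = grid_dim,
                  spacing = spacing, noise_hu = noise_hu,
                  seed = child_seed(seed, 100000L + i))
    })
  })
}

#' Emulate the stage-1 candidate detectors
#'
#' Stands in for the union of region-proposal detectors feeding the
#' false-positive-reduction stage: every true nodule is recalled with
#' probability `sensitivity` (with centre jitter up to a quarter of its
#' diameter), and the remaining budget of `n_per_scan` candidates is placed
#' preferentially on bright structures (vessels, chest wall) where real
#' detectors generate their false positives. Labels follow the hit criterion
#' used by the FROC scorer: a candidate is positive when its centre lies
#' within `diameter / 2` of a true nodule centre.
#'
#' @param vol A [ct_volume()] in HU.
#' @param truth Annotation tibble for the scan (may have zero rows).
#' @param n_per_scan Total candidates to emit (default 750); must be at least
#'   the number of truths.
#' @param sensitivity Recall probability per truth in `[0, 1]`.
#' @param seed Integer seed.
#' @param scan_id Scan identifier; defaults to the truth table's id.
#' @return A candidate tibble: `seriesuid`, `coordX`, `coordY`, `coordZ`,
#'   `label`.
#' @export
propose_candidates <- function(vol, truth, n_per_scan = 750,
                               sensitivity = 0.95, seed = 1L,
                               scan_id = NULL) {
  stopifnot(is_ct_volume(vol))
  if (is.null(scan_id)) {
    scan_id <- if (nrow(truth) > 0) truth$seriesuid[1] else "scan"
  }
  if (n_per_scan < nrow(truth)) {
    stop("`n_per_scan` must be at least the number of truths", call. = FALSE)
  }
  with_seed(seed, {
    pts <- matrix(numeric(0), 0, 3)  # (x, y, z)
    if (nrow(truth) > 0) {
      recalled <- stats::runif(nrow(truth)) < sensitivity
      for (i in which(recalled)) {
        u <- random_unit_vector()
        jit <- u * stats::runif(1, 0, 0.25 * truth$diameter_mm[i])
        pts <- rbind(pts, c(truth$coordX[i] + jit[3],
                            truth$coordY[i] + jit[2],
                            truth$coordZ[i] + jit[1]))
      }
    }
    n_bg <- n_per_scan - nrow(pts)
    if (n_bg > 0) {
      bright <- which(vol$data > -500 & vol$data < 300)
      n_bright <- round(0.75 * n_bg)
      take <- c(
        if (length(bright) > 0) sample(bright, min(n_bright, n_bg),
                                       replace = TRUE) else integer(0),
        sample(length(vol$data), n_bg - min(n_bright, n_bg) *
                 (length(bright) > 0), replace = TRUE)
      )
      take <- take[seq_len(n_bg)]
      ai <- arrayInd(take, dim(vol$data)) - 1  # 0-based (k, j, i)
      jitter <- matrix(stats::runif(3 * n_bg, -0.5, 0.5), ncol = 3)
      w <- voxel_to_world(vol, ai + jitter)    # (x, y, z)
      pts <- rbind(pts, w)
    }
    cand <- tibble::tibble(
      seriesuid = rep(scan_id, nrow(pts)),
      coordX = pts[, 1], coordY = pts[, 2], coordZ = pts[, 3]
    )
    cand$label <- candidate_label(
      ifelse(hit_truth(cand, truth), "positive", "negative"))
    cand
  })
}

# TRUE per candidate when its centre lies inside any truth's bounding sphere.
hit_truth <- function(candidates, truth) {
  if (nrow(truth) == 0 || nrow(candidates) == 0) {
    return(rep(FALSE, nrow(candidates)))
  }
  hit <- rep(FALSE, nrow(candidates))
  for (i in seq_len(nrow(truth))) {
    d2 <- (candidates$coordX - truth$coordX[i])^2 +
      (candidates$coordY - truth$coordY[i])^2 +
      (candidates$coordZ - truth$coordZ[i])^2
    hit <- hit | d2 <= (truth$diameter_mm[i] / 2)^2
  }
  hit
}

#' Write a simulated dataset to disk
#'
#' Renders a set of scans and writes them as MetaImage volumes next to a
#' combined `annotations.csv` and a `manifest.csv` describing each scan.
#'
#' @param mode `"phantom"` or `"clinical"`.
#' @param n_scans Number of scans.
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param difficulty Clinical-mode mimic richness.
#' @param ... Passed to [phantom_layouts()] or [generate_clinical_scan()].
#' @return The manifest tibble, invisibly.
#' @export
simulate_dataset <- function(mode = c("phantom", "clinical"), n_scans, dir,
                             seed = 1L, difficulty = 1, ...) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_all <- list()
  manifest <- list()
  if (mode == "phantom") {
    layouts <- phantom_layouts(n_scans = n_scans, seed = seed, ...)
    for (i in seq_along(layouts)) {
      scan <- generate_phantom_scan(layouts[[i]])
      sid <- layouts[[i]]$scan_id
      write_volume(scan$volume, file.path(dir, paste0(sid, ".mhd")))
      ann_all[[i]] <- scan$annotations
      manifest[[i]] <- tibble::tibble(seriesuid = sid, mode = mode,
                                      n_nodules = nrow(scan$annotations))
    }
  } else {
    for (i in seq_len(n_scans)) {
      sid <- sprintf("clinical_%04d", i)
      scan <- generate_clinical_scan(seed = child_seed(seed, i),
                                     difficulty = difficulty,
                                     scan_id = sid, ...)
      write_volume(scan$volume, file.path(dir, paste0(sid, ".mhd")))
      ann_all[[i]] <- scan$annotations
      manifest[[i]] <- tibble::tibble(seriesuid = sid, mode = mode,
                                      n_nodules = nrow(scan$annotations))
    }
  }
  ann <- dplyr::bind_rows(ann_all)
  write_annotations(ann, file.path(dir, "annotations.csv"))
  mf <- dplyr::bind_rows(manifest)
  readr::write_csv(mf, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(mf)
}
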
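#' Preprocessing configuration
#'
#' The standard pipeline constants: resample every scan to a common voxel
#' grid of 2 mm slice spacing and 0.625 mm in-plane pixels, clip Hounsfield
#' intensities to `[-1000, 400]` and rescale to `[-1, 1]`, extract 30 mm
#' cubic regions of interest (15 x 48 x 48 voxels at the target spacing),
#' sample 1000 nodule-free negatives per scan and oversample nodule-positive
#' patches 250-fold to counter class imbalance.
#'
#' @param target_spacing Target voxel spacing `(z, y, x)` mm.
#' @param hu_window Clipping window `(lo, hi)` in HU.
#' @param roi_size_mm Cubic ROI edge length in mm.
#' @param negatives_per_scan Negative candidates sampled per scan.
#' @param positive_oversample Oversampling factor for positive ROIs.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(2, 0.625, 0.625),
                              hu_window = c(-1000, 400),
                              roi_size_mm = 30,
                              negatives_per_scan = 1000,
                              positive_oversample = 250) {
  stopifnot(length(hu_window) == 2L, hu_window[1] < hu_window[2],
            roi_size_mm > 0, all(target_spacing > 0))
  structure(
    list(target_spacing = as.numeric(target_spacing),
         hu_window = as.numeric(hu_window),
         roi_size_mm = roi_size_mm,
         negatives_per_scan = as.integer(negatives_per_scan),
         positive_oversample = as.integer(positive_oversample)),
    class = "preprocess_config"
  )
}

#' ROI patch dimensions implied by a configuration
#'
#' @param config A [preprocess_config()].
#' @return Integer `(nz, ny, nx)`; `(15, 48, 48)` for the default.
#' @export
roi_dims <- function(config = preprocess_config()) {
  as.integer(round(config$roi_size_mm / config$target_spacing))
}

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation onto a grid with the requested spacing. Output
#' dimensions are `round(dim * spacing / target)` per axis; the origin is
#' preserved and the first output voxel sits at the original origin.
#'
#' @param vol A [ct_volume()].
#' @param target_spacing Numeric length-3 `(z, y, x)` mm, strictly positive.
#' @return A resampled [ct_volume()].
#' @export
resample_volume <- function(vol, target_spacing = c(2, 0.625, 0.625)) {
  stopifnot(is_ct_volume(vol))
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing <= 0)) {
    stop("`target_spacing` must be strictly positive", call. = FALSE)
  }
  d <- dim(vol$data)
  new_d <- pmax(as.integer(round(d * vol$spacing / target_spacing)), 1L)
  # continuous source indices of each output sample, per axis
  src <- lapply(1:3, function(a) {
    (seq_len(new_d[a]) - 1) * target_spacing[a] / vol$spacing[a]
  })
  out <- trilinear_sample(vol$data, src[[1]], src[[2]], src[[3]])
  ct_volume(out, spacing = target_spacing, origin = vol$origin)
}

# Sample `arr` at the tensor grid given by continuous 0-based indices
# (kz x ky x kx); values outside the grid clamp to the border.
trilinear_sample <- function(arr, kz, ky, kx) {
  d <- dim(arr)
  f <- function(k, n) clip(k, 0, n - 1)
  kz <- f(kz, d[1]); ky <- f(ky, d[2]); kx <- f(kx, d[3])
  z0 <- floor(kz); y0 <- floor(ky); x0 <- floor(kx)
  z1 <- pmin(z0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  x1 <- pmin(x0 + 1, d[3] - 1)
  wz <- kz - z0; wy <- ky - y0; wx <- kx - x0
  nd <- c(length(kz), length(ky), length(kx))
  g <- function(zi, yi, xi) {
    arr[cbind(
      rep(zi + 1, times = nd[2] * nd[3]),
      rep(rep(yi + 1, each = nd[1]), times = nd[3]),
      rep(xi + 1, each = nd[1] * nd[2])
    )]
  }
  wzv <- rep(wz, times = nd[2] * nd[3])
  wyv <- rep(rep(wy, each = nd[1]), times = nd[3])
  wxv <- rep(wx, each = nd[1] * nd[2])
  v <-
    g(z0, y0, x0) * (1 - wzv) * (1 - wyv) * (1 - wxv) +
    g(z1, y0, x0) * wzv * (1 - wyv) * (1 - wxv) +
    g(z0, y1, x0) * (1 - wzv) * wyv * (1 - wxv) +
    g(z1, y1, x0) * wzv * wyv * (1 - wxv) +
    g(z0, y0, x1) * (1 - wzv) * (1 - wyv) * wxv +
    g(z1, y0, x1) * wzv * (1 - wyv) * wxv +
    g(z0, y1, x1) * (1 - wzv) * wyv * wxv +
    g(z1, y1, x1) * wzv * wyv * wxv
  array(v, dim = nd)
}

#' Clip and rescale Hounsfield intensities
#'
#' Maps HU values through `v -> 2 * (clip(v, lo, hi) - lo) / (hi - lo) - 1`,
#' so the window endpoints land exactly on -1 and +1.
#'
#' @param vol A [ct_volume()] in HU.
#' @param hu_window Numeric `(lo, hi)`.
#' @return A [ct_volume()] with values in `[-1, 1]`.
#' @export
#' @examples
#' v <- ct_volume(array(c(-1000, -300, 400, 1000), c(1, 2, 2)))
#' range(normalize_intensity(v)$data)
normalize_intensity <- function(vol, hu_window = c(-1000, 400)) {
  stopifnot(is_ct_volume(vol), hu_window[1] < hu_window[2])
  lo <- hu_window[1]; hi <- hu_window[2]
  data <- 2 * (clip(vol$data, lo, hi) - lo) / (hi - lo) - 1
  ct_volume(data, spacing = vol$spacing, origin = vol$origin)
}

#' Extract a cubic ROI around a candidate
#'
#' Cuts a `roi_size_mm` cube (15 x 48 x 48 voxels at the default target
#' spacing) centred on the voxel nearest to `center_world`. For even patch
#' extents the centre voxel is the floor of the continuous index and the
#' window extends one voxel further on the positive side. Regions outside
#' the volume are padded with -1 (air after normalization).
#'
#' @param vol A normalized, resampled [ct_volume()].
#' @param center_world World point `(x, y, z)` mm.
#' @param roi_size_mm Cube edge in mm.
#' @return A 3D array of class `roi_patch` with attribute `center_world`.
#' @export
extract_roi <- function(vol, center_world, roi_size_mm = 30) {
  stopifnot(is_ct_volume(vol))
  nd <- as.integer(round(roi_size_mm / vol$spacing))
  idx <- world_to_voxel(vol, center_world)
  d <- dim(vol$data)
  if (any(idx < -nd) || any(idx > d - 1 + nd)) {
    stop("placement error: ROI centre lies more than one ROI outside the ",
         "volume", call. = FALSE)
  }
  center <- floor(idx)
  start <- center - floor((nd - 1) / 2)        # 0-based inclusive
  patch <- array(-1, dim = nd)
  src_lo <- pmax(start, 0)
  src_hi <- pmin(start + nd - 1, d - 1)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start + 1
    dst_hi <- src_hi - start + 1
    patch[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol$data[(src_lo[1]:src_hi[1]) + 1,
               (src_lo[2]:src_hi[2]) + 1,
               (src_lo[3]:src_hi[3]) + 1]
  }
  structure(patch, center_world = as.numeric(center_world),
            class = c("roi_patch", "array"))
}

#' Extract ROIs for a candidate table
#'
#' @param vol A normalized, resampled [ct_volume()].
#' @param candidates Candidate tibble (`seriesuid`, `coordX/Y/Z`, optionally
#'   `label`).
#' @param roi_size_mm Cube edge in mm.
#' @return The candidate tibble with a `patch` list-column of
#'   `roi_patch` arrays.
#' @export
extract_rois <- function(vol, candidates, roi_size_mm = 30) {
  candidates$patch <- purrr::pmap(
    list(candidates$coordX, candidates$coordY, candidates$coordZ),
    function(x, y, z) extract_roi(vol, c(x, y, z), roi_size_mm)
  )
  candidates
}

#' Sample nodule-free negative candidates
#'
#' Draws `n` candidate centres uniformly over the lung parenchyma (voxels
#' darker than -600 HU inside the thorax, excluding outside air) such that a
#' `roi_size_mm` cube around each centre does not intersect the bounding
#' sphere of any true nodule. Deterministic given `seed`.
#'
#' @param vol A [ct_volume()] in HU.
#' @param truth Annotation tibble for the scan (may be empty).
#' @param n Number of negatives (default 1000).
#' @param seed Integer seed.
#' @param roi_size_mm ROI cube edge used for the non-overlap test.
#' @param scan_id Scan identifier for the output table.
#' @return A candidate tibble with `label == "negative"` for all rows.
#' @export
sample_negatives <- function(vol, truth, n = 1000, seed = 1L,
                             roi_size_mm = 30, scan_id = NULL) {
  stopifnot(is_ct_volume(vol), n >= 1)
  if (is.null(scan_id)) {
    scan_id <- if (nrow(truth) > 0) truth$seriesuid[1] else "scan"
  }
  with_seed(seed, {
    # parenchyma: dark voxels that are not the outside-air margin; identify
    # outside air cheaply as voxels darker than -975 touching the x borders
    dark <- vol$data < -600 & vol$data > -975
    pool <- which(dark)
    if (length(pool) < 10) pool <- seq_along(vol$data)
    half <- roi_size_mm / 2
    got <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(got) < n && tries < 50L) {
      tries <- tries + 1L
      m <- max(2L * (n - nrow(got)), 200L)
      take <- sample(pool, m, replace = TRUE)
      ai <- arrayInd(take, dim(vol$data)) - 1
      jitter <- matrix(stats::runif(3 * m, -0.5, 0.5), ncol = 3)
      w <- voxel_to_world(vol, ai + jitter)  # (x, y, z)
      ok <- rep(TRUE, m)
      for (i in seq_len(nrow(truth))) {
        # closest point of the ROI box to the truth centre
        dx <- pmax(abs(w[, 1] - truth$coordX[i]) - half, 0)
        dy <- pmax(abs(w[, 2] - truth$coordY[i]) - half, 0)
        dz <- pmax(abs(w[, 3] - truth$coordZ[i]) - half, 0)
        ok <- ok & (dx^2 + dy^2 + dz^2 > (truth$diameter_mm[i] / 2)^2)
      }
      got <- rbind(got, w[ok, , drop = FALSE])
    }
    if (nrow(got) < n) {
      stop("sampling error: admissible region too small to draw ", n,
           " non-overlapping negatives", call. = FALSE)
    }
    got <- got[seq_len(n), , drop = FALSE]
    tibble::tibble(
      seriesuid = rep(scan_id, n),
      coordX = got[, 1], coordY = got[, 2], coordZ = got[, 3],
      label = candidate_label(rep("negative", n))
    )
  })
}

#' Oversample positive ROIs
#'
#' Repeats every positive entry exactly `factor` times, leaves negatives
#' untouched, and shuffles the result reproducibly.
#'
#' @param rois A tibble with a `label` column (and typically a `patch`
#'   list-column).
#' @param factor Integer >= 1.
#' @param seed Shuffle seed.
#' @return The oversampled tibble.
#' @export
oversample_positives <- function(rois, factor = 250, seed = 1L) {
  stopifnot(factor >= 1, factor == round(factor))
  pos <- rois[rois$label == "positive", , drop = FALSE]
  neg <- rois[rois$label != "positive", , drop = FALSE]
  out <- dplyr::bind_rows(
    neg,
    pos[rep(seq_len(nrow(pos)), times = factor), , drop = FALSE]
  )
  with_seed(seed, out[sample.int(nrow(out)), , drop = FALSE])
}

#' Filter scans by acquisition quality
#'
#' Keeps scans whose slice thickness is at most `max_thickness_mm`, whose
#' slice z-positions advance by a uniform step (tolerance 1e-3 mm), and that
#' have no missing slices (gaps).
#'
#' @param metadata A tibble with columns `seriesuid`, `slice_thickness_mm`
#'   and a `z_positions` list-column of per-slice z coordinates.
#' @param max_thickness_mm Threshold (default 2.5 mm); thicker scans drop.
#' @param tol Uniformity tolerance in mm.
#' @return The kept rows of `metadata`.
#' @export
filter_scans <- function(metadata, max_thickness_mm = 2.5, tol = 1e-3) {
  keep <- purrr::map2_lgl(
    metadata$slice_thickness_mm, metadata$z_positions,
    function(th, z) {
      if (th > max_thickness_mm) return(FALSE)
      if (length(z) < 2) return(TRUE)
      dz <- diff(sort(z))
      max(abs(dz - dz[1])) <= tol
    }
  )
  metadata[keep, , drop = FALSE]
}
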
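#' Volumetric CT container
#'
#' A `ct_volume` bundles a 3D voxel grid with its physical geometry. The
#' array is stored in `(z, y, x)` axis order (slices, rows, columns), while
#' `spacing` and `origin` are given per axis in the same order, in
#' millimetres. World coordinates follow the LPS convention of the MetaImage
#' ecosystem and voxel indices are 0-based; direction cosines are assumed to
#' be the identity.
#'
#' @param data Numeric 3D array, dimensions `(nz, ny, nx)`. Values are
#'   Hounsfield units for raw scans or normalized intensities in `[-1, 1]`
#'   after [normalize_intensity()].
#' @param spacing Numeric length-3, voxel size in mm as `(z, y, x)`. Must be
#'   strictly positive.
#' @param origin Numeric length-3, world position in mm of voxel `(0, 0, 0)`,
#'   as `(z, y, x)`.
#'
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' vol <- ct_volume(array(-1000, c(4, 6, 6)), spacing = c(2, 0.625, 0.625))
#' dim(vol$data)
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (z, y, x); got ", length(dim(data)),
         " dimensions", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (z, y, x)",
         call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (z, y, x)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume data must be finite", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels (z, y, x)\n  spacing: %s mm\n  origin:  %s mm\n  range:   [%.6g, %.6g]\n",
    d[1], d[2], d[3],
    paste(signif(x$spacing, 6), collapse = " x "),
    paste(signif(x$origin, 6), collapse = ", "),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' World/voxel coordinate transforms
#'
#' Convert between world coordinates in mm (given as `(x, y, z)`, the order
#' used by the candidate CSV dialect) and continuous 0-based voxel indices in
#' `(k, j, i)` = `(z, y, x)` order. `world_to_voxel()` performs no rounding;
#' indices outside the grid are legal outputs and left to the caller.
#'
#' @param vol A [ct_volume()].
#' @param p_world Numeric length-3 world point `(x, y, z)` in mm, or an
#'   n-by-3 matrix of such points.
#' @param index Numeric length-3 continuous voxel index `(k, j, i)`
#'   (z, y, x), or an n-by-3 matrix.
#'
#' @return For `world_to_voxel()`, continuous voxel indices `(k, j, i)`; for
#'   `voxel_to_world()`, world coordinates `(x, y, z)` in mm. Matrix in, matrix
#'   out.
#' @export
#' @examples
#' vol <- ct_volume(array(0, c(10, 10, 10)), spacing = c(2, 0.625, 0.625))
#' world_to_voxel(vol, c(6.25, 6.25, 4))   # -> (2, 10, 10)
world_to_voxel <- function(vol, p_world) {
  stopifnot(is_ct_volume(vol))
  p <- rbind_points(p_world)
  # CSV order (x, y, z) -> internal (z, y, x)
  pz <- p[, c(3, 2, 1), drop = FALSE]
  idx <- sweep(sweep(pz, 2, vol$origin, "-"), 2, vol$spacing, "/")
  colnames(idx) <- c("k", "j", "i")
  drop_points(idx, p_world)
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, index) {
  stopifnot(is_ct_volume(vol))
  idx <- rbind_points(index)
  pz <- sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
  out <- pz[, c(3, 2, 1), drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  drop_points(out, index)
}

rbind_points <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    p
  } else {
    stopifnot(length(p) == 3L)
    matrix(as.numeric(p), nrow = 1L)
  }
}

drop_points <- function(out, input) {
  if (is.matrix(input)) out else drop(out)
}
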
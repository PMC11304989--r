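# Internal numerical utilities shared by the simulator, preprocessing and
# augmentation code.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are pure functions of
# (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      get(".Random.seed", envir = env)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = env, inherits = FALSE)) {
          rm(".Random.seed", envir = env)
        }
      } else {
        assign(".Random.seed", old, envir = env)
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stream tag, staying inside
# 32-bit integer range.
child_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 48271 + tag) %% 2147483587L) + 1L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coordinate grids (mm offsets from a reference voxel) for a (nz, ny, nx)
# array with spacing (z, y, x). Returns arrays of the same shape.
coord_grids <- function(dims, spacing, center_index = (dims - 1) / 2) {
  z <- (seq_len(dims[1]) - 1 - center_index[1]) * spacing[1]
  y <- (seq_len(dims[2]) - 1 - center_index[2]) * spacing[2]
  x <- (seq_len(dims[3]) - 1 - center_index[3]) * spacing[3]
  list(
    z = array(rep(z, times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims),
    x = array(rep(x, each = dims[1] * dims[2]), dim = dims)
  )
}

# Separable Gaussian blur of a 3D array; sigma_vox per axis (z, y, x).
# Edge handling replicates border values.
gauss_blur3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(2.5 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    arr <- blur_axis(arr, k, axis)
  }
  arr
}

blur_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  n <- d[axis]
  out <- array(0, dim = d)
  idx_all <- seq_len(n)
  for (o in seq_along(kernel)) {
    shift <- o - 1L - half
    src <- clip(idx_all + shift, 1L, n)
    out <- out + kernel[o] * index_axis(arr, src, axis)
  }
  out
}

index_axis <- function(arr, idx, axis) {
  switch(axis,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE]
  )
}

# Low-frequency multiplicative-free texture field: smoothed white noise
# rescaled to unit standard deviation (zero mean).
smooth_noise_field <- function(dims, sigma_vox) {
  f <- gauss_blur3d(array(stats::rnorm(prod(dims)), dim = dims), sigma_vox)
  f <- f - mean(f)
  sdf <- stats::sd(as.vector(f))
  if (sdf > 0) f / sdf else f
}
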
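#' Parameterized 3D patch augmentations
#'
#' Stochastic, label-preserving perturbations of normalized ROI patches.
#' Two strengths drive the semi-supervised consistency objective:
#'
#' * **weak** — random axis flips (in-plane and/or z) plus an integer-voxel
#'   translation of at most 10% of the patch extent per axis;
#' * **strong** — a weak augmentation followed by one operator drawn
#'   uniformly from the strong menu: in-plane rotation (up to
#'   `30 * magnitude` degrees), isotropic rescale (`1 +/- 0.2 * magnitude`),
#'   additive Gaussian noise (sd up to `0.1 * magnitude`), intensity
#'   scale/shift (`+/- 0.2 * magnitude`), Gaussian blur (sigma up to
#'   `magnitude` voxels), or cutout (a cube up to 25% of each extent set to
#'   -1).
#'
#' The labeled stream uses [labeled_augment()]: one operator selected
#' uniformly from the identity plus the full menu. All outputs keep the
#' input shape and are re-clipped to `[-1, 1]`; every function is a pure
#' function of `(patch, seed)`.
#'
#' @param patch A 3D array in `[-1, 1]` (an ROI patch).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param magnitude Augmentation strength in `[0, 1]`. Magnitude 0 makes
#'   [weak_augment()] the identity and [strong_augment()] equal to its weak
#'   part.
#' @param menu Character vector of operator names for the strong stage; see
#'   [augment_menu()].
#' @return The augmented patch, same dimensions and class.
#' @name augmentations
NULL

#' Augmentation operator menus
#'
#' @return `augment_menu("weak")` is `c("flip", "translate")`;
#'   `augment_menu("strong")` the heavier operators;
#'   `augment_menu("full")` their union.
#' @param kind One of `"weak"`, `"strong"`, `"full"`.
#' @export
augment_menu <- function(kind = c("full", "weak", "strong")) {
  kind <- match.arg(kind)
  weak <- c("flip", "translate")
  strong <- c("rotate", "scale", "noise", "intensity", "blur", "cutout")
  switch(kind, weak = weak, strong = strong, full = c(weak, strong))
}

#' @rdname augmentations
#' @export
weak_augment <- function(patch, seed = NULL, magnitude = 1) {
  with_seed(seed, {
    if (magnitude <= 0) return(keep_attrs(patch, patch))
    keep_attrs(weak_core(patch, magnitude), patch)
  })
}

# Weak stage drawing from the current RNG stream; shared by weak_augment()
# and strong_augment() so the two agree at strong magnitude 0.
weak_core <- function(patch, magnitude = 1) {
  flips <- stats::runif(3) < 0.5
  for (ax in which(flips)) patch <- flip_axis(patch, ax)
  d <- dim(patch)
  max_shift <- floor(0.1 * magnitude * d)
  shift <- vapply(max_shift, function(m) {
    if (m < 1) 0L else sample(seq.int(-m, m), 1)
  }, integer(1))
  translate_patch(patch, shift)
}

#' @rdname augmentations
#' @export
strong_augment <- function(patch, seed = NULL, magnitude = 1,
                           menu = augment_menu("strong")) {
  unknown <- setdiff(menu, augment_menu("full"))
  if (length(unknown) > 0) {
    stop("unknown operator name(s) in menu: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    out <- weak_core(patch, magnitude = 1)
    if (magnitude > 0) {
      op <- menu[sample.int(length(menu), 1)]
      out <- apply_aug_op(out, op, magnitude)
    }
    keep_attrs(clip(out, -1, 1), patch)
  })
}

#' @rdname augmentations
#' @export
labeled_augment <- function(patch, seed = NULL, magnitude = 1,
                            menu = augment_menu("full")) {
  unknown <- setdiff(menu, augment_menu("full"))
  if (length(unknown) > 0) {
    stop("unknown operator name(s) in menu: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    choice <- sample.int(length(menu) + 1L, 1) - 1L  # 0 = identity
    out <- if (choice == 0L) patch else {
      apply_aug_op(patch, menu[choice], magnitude)
    }
    keep_attrs(clip(out, -1, 1), patch)
  })
}

keep_attrs <- function(out, template) {
  attributes(out) <- attributes(template)
  out
}

# Dispatch one named operator, drawing its strength from the current stream.
apply_aug_op <- function(patch, op, magnitude) {
  d <- dim(patch)
  switch(op,
    flip = {
      flips <- stats::runif(3) < 0.5
      for (ax in which(flips)) patch <- flip_axis(patch, ax)
      patch
    },
    translate = {
      max_shift <- floor(0.1 * magnitude * d)
      shift <- vapply(max_shift, function(m) {
        if (m < 1) 0L else sample(seq.int(-m, m), 1)
      }, integer(1))
      translate_patch(patch, shift)
    },
    rotate = {
      angle <- stats::runif(1, -30, 30) * magnitude * pi / 180
      rotate_inplane(patch, angle)
    },
    scale = {
      s <- 1 + stats::runif(1, -0.2, 0.2) * magnitude
      scale_patch(patch, s)
    },
    noise = {
      sd <- stats::runif(1, 0, 0.1 * magnitude)
      patch + stats::rnorm(length(patch), sd = sd)
    },
    intensity = {
      s <- 1 + stats::runif(1, -0.2, 0.2) * magnitude
      t <- stats::runif(1, -0.2, 0.2) * magnitude
      patch * s + t
    },
    blur = {
      sigma <- stats::runif(1, 0, 1) * magnitude
      if (sigma < 0.05) patch else gauss_blur3d(patch, rep(sigma, 3))
    },
    cutout = {
      edge <- pmax(floor(0.25 * magnitude * d), 0L)
      if (any(edge < 1)) return(patch)
      start <- vapply(seq_len(3), function(a) {
        sample.int(d[a] - edge[a] + 1L, 1)
      }, integer(1))
      patch[start[1]:(start[1] + edge[1] - 1),
            start[2]:(start[2] + edge[2] - 1),
            start[3]:(start[3] + edge[3] - 1)] <- -1
      patch
    },
    stop("unknown operator: ", op, call. = FALSE)
  )
}

flip_axis <- function(patch, axis) {
  d <- dim(patch)
  idx <- rev(seq_len(d[axis]))
  out <- index_axis(patch, idx, axis)
  dim(out) <- d
  out
}

# Integer-voxel translation; exposed voxels take the pad value -1.
translate_patch <- function(patch, shift, pad = -1) {
  d <- dim(patch)
  out <- array(pad, dim = d)
  src_lo <- pmax(1 - shift, 1); src_hi <- pmin(d - shift, d)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo + shift; dst_hi <- src_hi + shift
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    patch[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

# Scattered trilinear sampling at 0-based continuous indices (equal-length
# vectors); points outside the grid return `outside`.
sample_at <- function(arr, kz, ky, kx, outside = -1) {
  d <- dim(arr)
  inb <- kz >= 0 & kz <= d[1] - 1 & ky >= 0 & ky <= d[2] - 1 &
    kx >= 0 & kx <= d[3] - 1
  out <- rep(outside, length(kz))
  if (!any(inb)) return(out)
  kz <- kz[inb]; ky <- ky[inb]; kx <- kx[inb]
  z0 <- floor(kz); y0 <- floor(ky); x0 <- floor(kx)
  z1 <- pmin(z0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  x1 <- pmin(x0 + 1, d[3] - 1)
  wz <- kz - z0; wy <- ky - y0; wx <- kx - x0
  g <- function(zi, yi, xi) arr[cbind(zi + 1, yi + 1, xi + 1)]
  v <-
    g(z0, y0, x0) * (1 - wz) * (1 - wy) * (1 - wx) +
    g(z1, y0, x0) * wz * (1 - wy) * (1 - wx) +
    g(z0, y1, x0) * (1 - wz) * wy * (1 - wx) +
    g(z1, y1, x0) * wz * wy * (1 - wx) +
    g(z0, y0, x1) * (1 - wz) * (1 - wy) * wx +
    g(z1, y0, x1) * wz * (1 - wy) * wx +
    g(z0, y1, x1) * (1 - wz) * wy * wx +
    g(z1, y1, x1) * wz * wy * wx
  out[inb] <- v
  out
}

# In-plane (y, x) rotation about the patch centre, bilinear per slice.
# Rotations stay in-plane because the z spacing of ROI patches is coarse.
rotate_inplane <- function(patch, angle) {
  d <- dim(patch)
  cy <- (d[2] - 1) / 2; cx <- (d[3] - 1) / 2
  yy <- rep(seq_len(d[2]) - 1 - cy, times = d[3])
  xx <- rep(seq_len(d[3]) - 1 - cx, each = d[2])
  sy <- cy + cos(angle) * yy - sin(angle) * xx
  sx <- cx + sin(angle) * yy + cos(angle) * xx
  kz <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  ky <- rep(sy, each = d[1])
  kx <- rep(sx, each = d[1])
  array(sample_at(patch, kz, ky, kx), dim = d)
}

# Isotropic rescale about the patch centre; s > 1 zooms in.
scale_patch <- function(patch, s) {
  d <- dim(patch)
  ctr <- (d - 1) / 2
  ax <- lapply(1:3, function(a) ctr[a] + (seq_len(d[a]) - 1 - ctr[a]) / s)
  kz <- rep(ax[[1]], times = d[2] * d[3])
  ky <- rep(rep(ax[[2]], each = d[1]), times = d[3])
  kx <- rep(ax[[3]], each = d[1] * d[2])
  array(sample_at(patch, kz, ky, kx), dim = d)
}

#' Augmentation policy
#'
#' A small config object tying a stream kind to its operator menu and
#' magnitude, so the training loop and experiment harness can be driven by
#' configuration instead of code edits.
#'
#' @param kind `"weak"`, `"strong"` or `"labeled"`.
#' @param magnitude Strength in `[0, 1]`.
#' @param menu Operator names; defaults to the canonical menu for `kind`.
#'   The weak menu is fixed to flip + translate; a strong menu must add at
#'   least one heavier operator; the labeled policy implicitly includes the
#'   identity.
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(kind = c("weak", "strong", "labeled"),
                           magnitude = 1, menu = NULL) {
  kind <- match.arg(kind)
  if (is.null(menu)) {
    menu <- switch(kind, weak = augment_menu("weak"),
                   strong = augment_menu("strong"),
                   labeled = augment_menu("full"))
  }
  if (kind == "weak" && !setequal(menu, augment_menu("weak"))) {
    stop("the weak menu is fixed to {flip, translate}", call. = FALSE)
  }
  if (kind == "strong" && length(setdiff(menu, augment_menu("weak"))) == 0) {
    stop("a strong menu needs at least one operator beyond flip/translate",
         call. = FALSE)
  }
  stopifnot(magnitude >= 0, magnitude <= 1)
  structure(list(kind = kind, magnitude = magnitude, menu = menu),
            class = "augment_policy")
}

#' Apply an augmentation policy to a patch
#'
#' @param patch A 3D patch array.
#' @param policy An [augment_policy()].
#' @param seed Integer seed.
#' @return The augmented patch.
#' @export
apply_augment <- function(patch, policy, seed = NULL) {
  switch(policy$kind,
    weak = weak_augment(patch, seed, policy$magnitude),
    strong = strong_augment(patch, seed, policy$magnitude,
                            menu = setdiff(policy$menu, augment_menu("weak"))),
    labeled = labeled_augment(patch, seed, policy$magnitude,
                              menu = policy$menu)
  )
}
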
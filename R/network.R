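#' Network configuration for the FP-reduction classifier
#'
#' Three convolutional blocks (32, 64, 128 kernels of size 3 x 3 x 3, two
#' convolutions per block, each followed by a leaky rectifier), 2 x 2 x 2 max
#' pooling after each block, dropout 0.3 inside the blocks, then a dense
#' block of global 3D average pooling and two fully connected layers of 128
#' nodes with dropout 0.9, ending in a single sigmoid logit.
#'
#' @param conv_kernels Kernel counts per block, length 3.
#' @param convs_per_block Convolutions per block (fixed at 2).
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @param conv_dropout Dropout rate inside convolutional blocks.
#' @param fc_nodes Width of the two fully connected layers.
#' @param fc_dropout Dropout rate in the dense block.
#' @param input_shape Patch shape `(nz, ny, nx)`; every axis must survive
#'   three rounds of floor-halving.
#' @return A `network_config` list.
#' @export
network_config <- function(conv_kernels = c(32, 64, 128),
                           convs_per_block = 2,
                           leaky_slope = 0.01,
                           conv_dropout = 0.3,
                           fc_nodes = c(128, 128),
                           fc_dropout = 0.9,
                           input_shape = c(15, 48, 48)) {
  stopifnot(length(conv_kernels) == 3L, convs_per_block == 2,
            length(fc_nodes) == 2L,
            conv_dropout >= 0, conv_dropout < 1,
            fc_dropout >= 0, fc_dropout < 1)
  input_shape <- as.integer(input_shape)
  d <- input_shape
  for (p in 1:3) {
    d <- d %/% 2L
    if (any(d < 1L)) {
      stop("input shape not poolable three times along axis ",
           which(d < 1L)[1], " (z=1, y=2, x=3)", call. = FALSE)
    }
  }
  structure(
    list(conv_kernels = as.integer(conv_kernels),
         convs_per_block = 2L, leaky_slope = leaky_slope,
         conv_dropout = conv_dropout, fc_nodes = as.integer(fc_nodes),
         fc_dropout = fc_dropout, input_shape = input_shape),
    class = "network_config"
  )
}

#' Build the FP-reduction network
#'
#' Initializes weights with He-style scaling for the leaky rectifier,
#' reproducibly from `seed`. The layer census is exactly 6 convolutional
#' layers, 3 max-pooling stages, 1 global average pooling and 2 fully
#' connected layers before the scalar sigmoid head.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fpr_net` holding the configuration, the
#'   parameter list and the per-stage spatial shapes.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  with_seed(seed, {
    shapes <- list(config$input_shape)
    for (b in 1:3) shapes[[b + 1]] <- shapes[[b]] %/% 2L
    channels <- c(1L, config$conv_kernels)
    he <- function(nrow, ncol, fan_in) {
      matrix(stats::rnorm(nrow * ncol,
                          sd = sqrt(2 / ((1 + config$leaky_slope^2) * fan_in))),
             nrow, ncol)
    }
    conv <- list()
    li <- 0L
    for (b in 1:3) {
      for (cix in 1:2) {
        li <- li + 1L
        cin <- if (cix == 1) channels[b] else channels[b + 1]
        cout <- channels[b + 1]
        conv[[li]] <- list(W = he(27L * cin, cout, 27 * cin),
                           b = numeric(cout))
      }
    }
    nf <- config$conv_kernels[3]
    fc <- list(
      list(W = he(nf, config$fc_nodes[1], nf), b = numeric(config$fc_nodes[1])),
      list(W = he(config$fc_nodes[1], config$fc_nodes[2], config$fc_nodes[1]),
           b = numeric(config$fc_nodes[2]))
    )
    head <- list(w = stats::rnorm(config$fc_nodes[2],
                                  sd = sqrt(1 / config$fc_nodes[2])),
                 b = 0)
    structure(
      list(config = config,
           params = list(conv = conv, fc = fc, head = head),
           shapes = shapes),
      class = "fpr_net"
    )
  })
}

#' @export
print.fpr_net <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf(
    "<fpr_net> input %s | %d conv (%s kernels) + %d max-pool + %d avg-pool + %d fc -> sigmoid\n  parameters: %d\n",
    paste(x$config$input_shape, collapse = "x"),
    cen[["conv"]], paste(x$config$conv_kernels, collapse = "/"),
    cen[["max_pool"]], cen[["avg_pool"]], cen[["fc"]],
    n_parameters(x)))
  invisible(x)
}

#' Layer census of a network
#'
#' @param net An `fpr_net`.
#' @return Named integer vector with counts of `conv`, `max_pool`,
#'   `avg_pool` and `fc` layers (the sigmoid output head is counted
#'   separately as `output`).
#' @export
layer_census <- function(net) {
  c(conv = length(net$params$conv), max_pool = 3L, avg_pool = 1L,
    fc = length(net$params$fc), output = 1L)
}

n_parameters <- function(net) {
  length(flatten_params(net$params))
}

# ---- geometry caches --------------------------------------------------------
# im2col linear indices for a (d1, d2, d3) grid with 3^3 kernel and padding
# 1: a list of 27 integer vectors, each mapping output voxel v to its source
# voxel in the padded grid (column-major, z fastest).

the_geom_cache <- new.env(parent = emptyenv())

conv_geometry <- function(d) {
  key <- paste0("c", paste(d, collapse = "_"))
  got <- the_geom_cache[[key]]
  if (!is.null(got)) return(got)
  dp <- d + 2L
  v <- prod(d)
  z <- rep(seq_len(d[1]), times = d[2] * d[3])        # 1-based interior
  y <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  x <- rep(seq_len(d[3]), each = d[1] * d[2])
  offs <- vector("list", 27L)
  o <- 0L
  for (ox in 0:2) for (oy in 0:2) for (oz in 0:2) {
    o <- o + 1L
    # 1-based index into the padded grid for output voxel (z, y, x)
    offs[[o]] <- (z + oz) + dp[1] * ((y + oy) - 1L) +
      dp[1] * dp[2] * ((x + ox) - 1L)
  }
  interior <- (z + 1L) + dp[1] * ((y + 1L) - 1L) +
    dp[1] * dp[2] * ((x + 1L) - 1L)
  geom <- list(offsets = offs, interior = interior, dp = dp, v = v)
  the_geom_cache[[key]] <- geom
  geom
}

pool_geometry <- function(d) {
  key <- paste0("p", paste(d, collapse = "_"))
  got <- the_geom_cache[[key]]
  if (!is.null(got)) return(got)
  d2 <- d %/% 2L
  v2 <- prod(d2)
  z <- rep(seq_len(d2[1]), times = d2[2] * d2[3])
  y <- rep(rep(seq_len(d2[2]), each = d2[1]), times = d2[3])
  x <- rep(seq_len(d2[3]), each = d2[1] * d2[2])
  src <- matrix(0L, v2, 8L)
  o <- 0L
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    o <- o + 1L
    src[, o] <- (2L * z - 1L + oz) + d[1] * (2L * y - 2L + oy) +
      d[1] * d[2] * (2L * x - 2L + ox)
  }
  geom <- list(src = src, d2 = d2, v2 = v2)
  the_geom_cache[[key]] <- geom
  geom
}

# ---- forward / backward -----------------------------------------------------
# Activations are stored voxel-major: a (V, C) matrix per sample. Weights of
# a conv layer form a (27 * C_in, C_out) matrix whose row (o - 1) * C_in + c
# multiplies input channel c at kernel offset o, so the convolution is the
# single product `col %*% W` with col of shape (V, 27 * C_in).

# add a per-column bias without the sweep() overhead
sweep_add_cols <- function(m, b) {
  m + rep(b, each = nrow(m))
}

leaky <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}
leaky_grad <- function(x, slope) {
  g <- (x >= 0) * 1
  g[g == 0] <- slope
  g
}

# Batched geometry: the per-sample index vectors shifted for n samples
# stacked vertically (sample-major row blocks).
batch_geometry <- function(d, n) {
  key <- paste0("b", paste(d, collapse = "_"), "_", n)
  got <- the_geom_cache[[key]]
  if (!is.null(got)) return(got)
  gc1 <- conv_geometry(d)
  gp1 <- pool_geometry(d)
  vp <- prod(gc1$dp)
  shift_p <- rep((seq_len(n) - 1L) * vp, each = gc1$v)
  shift_v <- rep((seq_len(n) - 1L) * gc1$v, each = gp1$v2)
  geom <- list(
    offsets = lapply(gc1$offsets, function(o) rep(o, n) + shift_p),
    interior = rep(gc1$interior, n) + shift_p,
    vp = vp, v = gc1$v, n = n,
    pool_src = gp1$src[rep(seq_len(gp1$v2), n), ] +
      rep((seq_len(n) - 1L) * gc1$v, each = gp1$v2),
    d2 = gp1$d2, v2 = gp1$v2
  )
  the_geom_cache[[key]] <- geom
  geom
}

# Forward pass for a chunk of n samples stacked vertically: activations are
# ((n * V), C) matrices. `drop_masks` carries pre-drawn dropout keep masks
# (NULL in evaluation mode). Returns the (n, C) pooled feature matrix plus
# a cache for backprop.
forward_conv_stack <- function(net, x, n, drop_masks = NULL,
                               keep_cache = TRUE) {
  cfg <- net$config
  d <- cfg$input_shape
  cache <- list()
  li <- 0L
  for (b in 1:3) {
    geom <- batch_geometry(d, n)
    for (cix in 1:2) {
      li <- li + 1L
      p <- net$params$conv[[li]]
      cin <- ncol(x)
      xp <- matrix(0, geom$vp * n, cin)
      xp[geom$interior, ] <- x
      col <- matrix(0, geom$v * n, 27L * cin)
      for (o in 1:27) {
        col[, ((o - 1L) * cin + 1L):(o * cin)] <-
          xp[geom$offsets[[o]], , drop = FALSE]
      }
      pre <- sweep_add_cols(col %*% p$W, p$b)      # ((n V), C_out)
      if (keep_cache) {
        cache[[paste0("conv", li)]] <- list(col = col, pre = pre, d = d)
      }
      x <- leaky(pre, cfg$leaky_slope)
    }
    ch <- ncol(x)
    pooled <- x[geom$pool_src[, 1], , drop = FALSE]
    arg <- matrix(geom$pool_src[, 1], nrow(pooled), ch)
    for (o in 2:8) {
      cand <- x[geom$pool_src[, o], , drop = FALSE]
      better <- cand > pooled
      pooled[better] <- cand[better]
      arg[better] <- matrix(geom$pool_src[, o], nrow(pooled), ch)[better]
    }
    if (!is.null(drop_masks)) pooled <- pooled * drop_masks[[b]]
    if (keep_cache) {
      cache[[paste0("pool", b)]] <- list(
        arg = arg, v_in = geom$v * n,
        mask = if (is.null(drop_masks)) NULL else drop_masks[[b]])
    }
    x <- pooled
    d <- geom$d2
  }
  v3 <- prod(d)
  feats <- rowsum(x, group = rep(seq_len(n), each = v3)) / v3
  if (keep_cache) cache$avg_v <- v3
  list(feats = feats, cache = cache)
}

backward_conv_stack <- function(net, cache, grad_feats, n) {
  cfg <- net$config
  grads <- vector("list", 6L)
  v3 <- cache$avg_v
  gx <- grad_feats[rep(seq_len(n), each = v3), , drop = FALSE] / v3
  li <- 6L
  for (b in 3:1) {
    pc <- cache[[paste0("pool", b)]]
    if (!is.null(pc$mask)) gx <- gx * pc$mask
    gin <- matrix(0, pc$v_in, ncol(gx))
    lin <- as.vector(pc$arg + rep((seq_len(ncol(gx)) - 1L) * pc$v_in,
                                  each = nrow(gx)))
    gin[lin] <- gin[lin] + as.vector(gx)     # argmax sources are unique
    gx <- gin
    for (cix in 2:1) {
      cc <- cache[[paste0("conv", li)]]
      geom <- batch_geometry(cc$d, n)
      gpre <- gx * leaky_grad(cc$pre, cfg$leaky_slope)  # ((n V), C_out)
      grads[[li]] <- list(b = colSums(gpre),
                          W = crossprod(cc$col, gpre))  # (27 cin, C_out)
      cin <- ncol(cc$col) %/% 27L
      gcol <- tcrossprod(gpre, net$params$conv[[li]]$W) # ((n V), 27 cin)
      gxp <- matrix(0, geom$vp * n, cin)
      for (o in 1:27) {
        cols <- ((o - 1L) * cin + 1L):(o * cin)
        idx <- geom$offsets[[o]]
        gxp[idx, ] <- gxp[idx, ] + gcol[, cols, drop = FALSE]
      }
      gx <- gxp[geom$interior, , drop = FALSE]
      li <- li - 1L
    }
  }
  grads
}

# Largest im2col buffer (doubles) per sample, used to pick a chunk size
# that bounds transient memory.
max_col_doubles <- function(cfg) {
  d <- cfg$input_shape
  channels <- c(1L, cfg$conv_kernels)
  worst <- 0
  for (b in 1:3) {
    v <- prod(d)
    worst <- max(worst, v * 27 * channels[b], v * 27 * channels[b + 1])
    d <- d %/% 2L
  }
  worst
}

conv_chunk_size <- function(cfg, budget = 4e7) {
  max(1L, min(64L, as.integer(budget %/% max_col_doubles(cfg))))
}

# Full-network forward over a batch (list of patches), chunked so the
# im2col buffers stay within a fixed memory budget. Returns scores and,
# when `training`, caches for backprop. Dropout masks are drawn from the
# current RNG stream.
net_forward <- function(net, patches, training = FALSE, keep_cache = training) {
  cfg <- net$config
  n <- length(patches)
  if (n == 0L) {
    return(list(scores = numeric(0), chunks = list(), fc_cache = NULL))
  }
  chunk <- conv_chunk_size(cfg)
  starts <- seq(1L, n, by = chunk)
  feats <- matrix(0, n, cfg$conv_kernels[3])
  chunks <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk - 1L, n)
    nc <- length(idx)
    x <- matrix(unlist(patches[idx], use.names = FALSE), ncol = 1L)
    masks <- NULL
    if (training && cfg$conv_dropout > 0) {
      masks <- lapply(1:3, function(b) {
        d2 <- net$shapes[[b + 1]]
        keep <- matrix(stats::runif(prod(d2) * nc * cfg$conv_kernels[b]) >=
                         cfg$conv_dropout,
                       prod(d2) * nc, cfg$conv_kernels[b])
        keep / (1 - cfg$conv_dropout)
      })
    }
    fs <- forward_conv_stack(net, x, nc, drop_masks = masks,
                             keep_cache = keep_cache)
    feats[idx, ] <- fs$feats
    chunks[[ci]] <- list(idx = idx, cache = fs$cache)
  }
  fc <- net$params$fc
  hd <- net$params$head
  mask1 <- mask2 <- NULL
  a0 <- feats
  z1 <- sweep_add_cols(a0 %*% fc[[1]]$W, fc[[1]]$b)
  a1 <- leaky(z1, cfg$leaky_slope)
  if (training && cfg$fc_dropout > 0) {
    mask1 <- matrix(stats::runif(length(a1)) >= cfg$fc_dropout,
                    nrow(a1), ncol(a1)) / (1 - cfg$fc_dropout)
    a1 <- a1 * mask1
  }
  z2 <- sweep_add_cols(a1 %*% fc[[2]]$W, fc[[2]]$b)
  a2 <- leaky(z2, cfg$leaky_slope)
  if (training && cfg$fc_dropout > 0) {
    mask2 <- matrix(stats::runif(length(a2)) >= cfg$fc_dropout,
                    nrow(a2), ncol(a2)) / (1 - cfg$fc_dropout)
    a2 <- a2 * mask2
  }
  logit <- drop(a2 %*% hd$w) + hd$b
  scores <- 1 / (1 + exp(-logit))
  fc_cache <- if (keep_cache) {
    list(a0 = a0, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
         mask1 = mask1, mask2 = mask2)
  }
  list(scores = scores, chunks = chunks, fc_cache = fc_cache)
}

# Backward from per-sample dL/dlogit. Returns gradient pytree matching
# net$params.
net_backward <- function(net, fwd, grad_logit) {
  cfg <- net$config
  fcc <- fwd$fc_cache
  hd <- net$params$head
  g_head_w <- drop(t(fcc$a2) %*% grad_logit)
  g_head_b <- sum(grad_logit)
  ga2 <- outer(grad_logit, hd$w)
  if (!is.null(fcc$mask2)) ga2 <- ga2 * fcc$mask2
  gz2 <- ga2 * leaky_grad(fcc$z2, cfg$leaky_slope)
  g_fc2_w <- t(fcc$a1) %*% gz2
  g_fc2_b <- colSums(gz2)
  ga1 <- gz2 %*% t(net$params$fc[[2]]$W)
  if (!is.null(fcc$mask1)) ga1 <- ga1 * fcc$mask1
  gz1 <- ga1 * leaky_grad(fcc$z1, cfg$leaky_slope)
  g_fc1_w <- t(fcc$a0) %*% gz1
  g_fc1_b <- colSums(gz1)
  gfeat <- gz1 %*% t(net$params$fc[[1]]$W)

  conv_g <- lapply(net$params$conv, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b))))
  for (ch in fwd$chunks) {
    gf <- gfeat[ch$idx, , drop = FALSE]
    if (all(gf == 0)) next
    gi <- backward_conv_stack(net, ch$cache, gf, length(ch$idx))
    for (l in seq_along(conv_g)) {
      conv_g[[l]]$W <- conv_g[[l]]$W + gi[[l]]$W
      conv_g[[l]]$b <- conv_g[[l]]$b + gi[[l]]$b
    }
  }
  list(conv = conv_g,
       fc = list(list(W = g_fc1_w, b = g_fc1_b),
                 list(W = g_fc2_w, b = g_fc2_b)),
       head = list(w = g_head_w, b = g_head_b))
}

#' Score ROI patches with a trained network
#'
#' Runs the classifier in evaluation mode (dropout inactive); one nodule
#' probability per patch, order preserved.
#'
#' @param object An `fpr_net` (or an `fpr_fit`, whose network is used).
#' @param patches A list of 3D arrays matching the configured input shape,
#'   or a tibble with a `patch` list-column.
#' @param ... Unused.
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
predict.fpr_net <- function(object, patches, ...) {
  if (is.data.frame(patches)) patches <- patches$patch
  if (length(patches) == 0L) return(numeric(0))
  shp <- object$config$input_shape
  for (p in patches) {
    if (!identical(dim(p), shp) && !identical(as.integer(dim(p)), shp)) {
      stop("patch shape ", paste(dim(p), collapse = "x"),
           " does not match network input ", paste(shp, collapse = "x"),
           call. = FALSE)
    }
  }
  net_forward(object, patches, training = FALSE, keep_cache = FALSE)$scores
}

# Flatten / unflatten parameter pytrees for the optimizer.
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

assign_flat <- function(params, flat) {
  rel <- utils::relist(flat, params)
  # relist preserves structure but drops matrix dims; restore them
  restore <- function(tpl, new) {
    if (is.list(tpl)) {
      for (k in seq_along(tpl)) tpl[[k]] <- restore(tpl[[k]], new[[k]])
      tpl
    } else {
      if (!is.null(dim(tpl))) dim(new) <- dim(tpl)
      new
    }
  }
  restore(params, rel)
}

# Adaptive-moment (Adam) update; state carries first/second moments.
adam_step <- function(flat, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
  }
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(flat = flat - lr * mhat / (sqrt(vhat) + eps), state = state)
}
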
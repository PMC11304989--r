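# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force FROC: enumerate every threshold, count detected truths and
# false positives directly from first principles.
brute_force_froc <- function(scores, is_tp, truth_id, n_scans, n_truths) {
  thr <- sort(unique(scores), decreasing = TRUE)
  t(vapply(thr, function(t) {
    sel <- scores >= t
    detected <- length(unique(truth_id[sel & is_tp]))
    fp <- sum(sel & !is_tp)
    c(threshold = t, fp_per_scan = fp / n_scans,
      sensitivity = detected / n_truths)
  }, numeric(3)))
}

# Textbook binary cross-entropy.
bce_oracle <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(ifelse(y == 1, log(p), log(1 - p)))
}

# Count 26-connected components of a logical 3D array by flood fill.
count_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(ai), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[mask[lin] & lab[lin] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  cur
}

# A delta-spike patch: single bright voxel on a flat background, for
# tracking translations.
spike_patch <- function(dims = c(10, 16, 16), at = dims %/% 2) {
  p <- array(-1, dims)
  p[at[1], at[2], at[3]] <- 1
  p
}

random_patch <- function(dims = c(10, 16, 16), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(prod(dims), -1, 1), dims)
}

# Small labeled ROI table (bright-core positives vs background negatives)
# used by the training acceptance checks.
make_acceptance_labeled <- function(n_per_class = 12, dims = c(8, 8, 8),
                                    seed = 1) {
  set.seed(seed)
  mk <- function(pos) {
    a <- array(stats::rnorm(prod(dims), -0.5, 0.15), dims)
    if (pos) a[3:6, 3:6, 3:6] <- a[3:6, 3:6, 3:6] + 1
    a
  }
  tibble::tibble(
    patch = c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
              lapply(seq_len(n_per_class), function(i) mk(FALSE))),
    label = rep(c("positive", "negative"), each = n_per_class)
  )
}
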
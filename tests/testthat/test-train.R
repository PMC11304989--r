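test_that("focal loss reproduces its closed-form values", {
  expect_equal(focal_loss(0.5, 1, alpha = 16, gamma = 2), 16 * 0.25 * log(2),
               tolerance = 1e-9)
  # perfect predictions drive the loss to zero
  expect_lt(focal_loss(1 - 1e-9, 1, 16, 2), 1e-15)
  expect_lt(focal_loss(1e-9, 0, 16, 2), 1e-15)
  expect_equal(focal_loss(numeric(0), numeric(0)), 0)
})

test_that("focal loss with alpha 1, gamma 0 equals binary cross-entropy", {
  set.seed(1)
  p <- runif(1000, 0.01, 0.99)
  y <- rbinom(1000, 1, 0.5)
  expect_equal(focal_loss(p, y, alpha = 1, gamma = 0), bce_oracle(p, y),
               tolerance = 1e-12)
})

test_that("the focal logit gradient matches numerical differentiation", {
  set.seed(2)
  z <- rnorm(200, sd = 2)
  y <- rbinom(200, 1, 0.5)
  p <- 1 / (1 + exp(-z))
  eps <- 1e-6
  num <- (focal_loss(1 / (1 + exp(-(z + eps))), y, 16, 2, reduce = "none") -
            focal_loss(1 / (1 + exp(-(z - eps))), y, 16, 2,
                       reduce = "none")) / (2 * eps)
  expect_equal(nodulefpr:::focal_grad_logit(p, y, 16, 2), num,
               tolerance = 1e-6)
})

test_that("the consistency gate applies the confidence threshold", {
  out <- consistency_loss(c(0.97, 0.60), c(0.9, 0.4), tau_c = 0.95)
  expect_equal(out$gate_mask, c(TRUE, FALSE))
  expect_equal(out$pseudo_targets[1], 1)
  # low scores are confident negatives
  out2 <- consistency_loss(0.03, 0.2, tau_c = 0.95)
  expect_true(out2$gate_mask)
  expect_equal(out2$pseudo_targets, 0)
  # nothing gated: lu is exactly zero
  out3 <- consistency_loss(c(0.6, 0.4, 0.5), c(0.1, 0.9, 0.5), tau_c = 0.95)
  expect_identical(out3$lu, 0)
})

test_that("the gated consistency value equals the focal loss of gated pairs", {
  weak <- c(0.99, 0.02, 0.7)
  strong <- c(0.8, 0.3, 0.9)
  out <- consistency_loss(weak, strong, tau_c = 0.95, alpha = 16, gamma = 2)
  expect_equal(out$lu, focal_loss(c(0.8, 0.3), c(1, 0), 16, 2))
})

test_that("pseudo-labels follow the teacher-score thresholds", {
  expect_equal(
    as.character(assign_pseudo_labels(c(0.005, 0.5, 0.995), 0.01, 0.99)),
    c("negative", "abstain", "positive"))
  # extreme thresholds label only exact endpoints
  got <- assign_pseudo_labels(c(0, 0.3, 1), lo = 0, hi = 1)
  expect_equal(as.character(got), c("negative", "abstain", "positive"))
  expect_length(assign_pseudo_labels(numeric(0)), 0L)
})

test_that("the combined loss is the weighted sum of its terms", {
  expect_equal(combined_loss(0.8, 0.4, 0.2, 0.5, 0.5), 1.1)
  expect_equal(combined_loss(0.8, 0.4, 0.2, 0, 0), 0.8)
  expect_equal(combined_loss(0, 0, 0), 0)
  expect_error(combined_loss(Inf, 0, 0))
})

make_toy_labeled <- function(n_per_class = 12, dims = c(8, 8, 8),
                             seed = 1) {
  set.seed(seed)
  mk <- function(pos) {
    a <- array(rnorm(prod(dims), -0.5, 0.15), dims)
    if (pos) a[3:6, 3:6, 3:6] <- a[3:6, 3:6, 3:6] + 1
    a
  }
  tibble::tibble(
    patch = c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
              lapply(seq_len(n_per_class), function(i) mk(FALSE))),
    label = rep(c("positive", "negative"), each = n_per_class)
  )
}

toy_net_cfg <- network_config(conv_kernels = c(2, 3, 4),
                              input_shape = c(8, 8, 8),
                              conv_dropout = 0.1, fc_dropout = 0.3,
                              fc_nodes = c(8, 8))

test_that("training without unlabeled data keeps lu and lp at zero", {
  fit <- train_fpr(make_toy_labeled(), NULL, net_config = toy_net_cfg,
                   epochs = 2, steps_per_epoch = 3, batch_labeled = 6,
                   seed = 3)
  expect_true(all(fit$history$lu == 0))
  expect_true(all(fit$history$lp == 0))
  expect_true(all(fit$history$gate_fraction == 0))
})

test_that("the logged loss decomposes exactly as ls + 0.5 lu + 0.5 lp", {
  lab <- make_toy_labeled()
  unlab <- tibble::tibble(patch = lab$patch[seq(1, 24, by = 2)])
  fit <- train_fpr(lab, unlab, net_config = toy_net_cfg,
                   epochs = 3, steps_per_epoch = 3, batch_labeled = 6,
                   batch_unlabeled = 6, seed = 4)
  expect_equal(fit$history$loss,
               fit$history$ls + 0.5 * fit$history$lu + 0.5 * fit$history$lp,
               tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  lab <- make_toy_labeled()
  f1 <- train_fpr(lab, NULL, net_config = toy_net_cfg, epochs = 2,
                  steps_per_epoch = 2, batch_labeled = 6, seed = 5)
  f2 <- train_fpr(lab, NULL, net_config = toy_net_cfg, epochs = 2,
                  steps_per_epoch = 2, batch_labeled = 6, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_identical(nodulefpr:::flatten_params(f1$net$params),
                   nodulefpr:::flatten_params(f2$net$params))
})

test_that("zero lambdas reduce the trainer to plain supervised training", {
  lab <- make_toy_labeled()
  unlab <- tibble::tibble(patch = lab$patch[1:6])
  sup <- train_fpr(lab, NULL, net_config = toy_net_cfg, epochs = 2,
                   steps_per_epoch = 2, batch_labeled = 6, seed = 6)
  # with lambda1 = lambda2 = 0 the unlabeled stream contributes nothing to
  # the parameter updates; ls histories agree step for step
  off <- train_fpr(lab, unlab,
                   loss_cfg = loss_config(lambda1 = 0, lambda2 = 0),
                   net_config = toy_net_cfg, epochs = 2,
                   steps_per_epoch = 2, batch_labeled = 6,
                   batch_unlabeled = 4, seed = 6)
  expect_equal(off$history$loss, off$history$ls, tolerance = 1e-12)
})

test_that("teacher pseudo-labels steer the pseudo-label term", {
  lab <- make_toy_labeled()
  teacher_fit <- train_fpr(lab, NULL, net_config = toy_net_cfg, epochs = 2,
                           steps_per_epoch = 3, batch_labeled = 8, seed = 7)
  unlab <- tibble::tibble(patch = make_toy_labeled(seed = 9)$patch)
  fit <- train_fpr(lab, unlab, net_config = toy_net_cfg, epochs = 2,
                   steps_per_epoch = 2, batch_labeled = 6,
                   batch_unlabeled = 6, seed = 8, teacher = teacher_fit$net)
  expect_s3_class(fit, "fpr_fit")
  expect_true(all(is.finite(fit$history$lp)))
})

test_that("pseudo-labelling at strict thresholds never exceeds the plain error rate", {
  # simulated teacher of known accuracy: scores drawn around the truth
  set.seed(10)
  truth <- rbinom(4000, 1, 0.5)
  raw <- plogis(qlogis(0.5 + (truth - 0.5) * 0.9) + rnorm(4000, sd = 1.5))
  plain_error <- mean((raw >= 0.5) != truth)
  labels <- assign_pseudo_labels(raw, 0.01, 0.99)
  assigned <- labels != "abstain"
  if (any(assigned)) {
    strict_error <- mean((labels[assigned] == "positive") != truth[assigned])
    expect_lte(strict_error, plain_error)
  }
})

test_that("tidy and glance summarise a fit", {
  fit <- train_fpr(make_toy_labeled(), NULL, net_config = toy_net_cfg,
                   epochs = 2, steps_per_epoch = 2, batch_labeled = 6,
                   seed = 11)
  td <- tidy(fit)
  expect_true(all(c("epoch", "term", "value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$n_parameters > 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
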
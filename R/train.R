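#' Loss configuration for semi-supervised training
#'
#' The composite objective is `L = ls + lambda1 * lu + lambda2 * lp`: a
#' supervised focal loss `ls` on the labeled stream, a confidence-gated
#' consistency loss `lu` between weakly and strongly augmented views of the
#' unlabeled stream, and a pseudo-label focal loss `lp` on unlabeled samples
#' that a phantom-trained teacher scored confidently before training.
#'
#' @param lambda1 Weight of the consistency term (default 0.5).
#' @param lambda2 Weight of the pseudo-label term (default 0.5).
#' @param tau_c Confidence gate on the weak view (default 0.95); a sample
#'   contributes to `lu` only when `max(p, 1 - p) >= tau_c`.
#' @param pseudo_lo,pseudo_hi Teacher-score thresholds assigning negative
#'   (`<= 0.01`) and positive (`>= 0.99`) pseudo-labels; scores in between
#'   abstain.
#' @param focal_alpha,focal_gamma Focal-loss parameters (defaults 16 and 2).
#' @param weight_decay L2 penalty coefficient on convolution kernel weights.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda1 = 0.5, lambda2 = 0.5, tau_c = 0.95,
                        pseudo_lo = 0.01, pseudo_hi = 0.99,
                        focal_alpha = 16, focal_gamma = 2,
                        weight_decay = 1e-4) {
  stopifnot(tau_c > 0, tau_c < 1, pseudo_lo < pseudo_hi,
            focal_alpha > 0, focal_gamma >= 0, weight_decay >= 0)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, tau_c = tau_c,
         pseudo_lo = pseudo_lo, pseudo_hi = pseudo_hi,
         focal_alpha = focal_alpha, focal_gamma = focal_gamma,
         weight_decay = weight_decay),
    class = "loss_config"
  )
}

#' Focal loss
#'
#' `FL(p, y) = -alpha * (1 - pt)^gamma * log(pt)` with `pt = p` when `y = 1`
#' and `pt = 1 - p` otherwise. With `alpha = 1, gamma = 0` this is binary
#' cross-entropy. Predictions are clamped to `(eps, 1 - eps)` so the log is
#' always finite.
#'
#' @param p Predicted probabilities.
#' @param y Labels in `{0, 1}` (recycled).
#' @param alpha Class-imbalance weight (> 0).
#' @param gamma Hard-example focusing exponent (>= 0).
#' @param reduce `"mean"` (default) or `"none"`.
#' @param eps Clamping epsilon.
#' @return Mean loss, or the per-sample vector when `reduce = "none"`.
#' @export
#' @examples
#' focal_loss(0.5, 1, alpha = 16, gamma = 2)   # 16 * 0.25 * log(2)
focal_loss <- function(p, y, alpha = 16, gamma = 2, reduce = c("mean", "none"),
                       eps = 1e-7) {
  reduce <- match.arg(reduce)
  stopifnot(all(y %in% c(0, 1)))
  p <- clip(p, eps, 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  l <- -alpha * (1 - pt)^gamma * log(pt)
  if (reduce == "mean") {
    if (length(l) == 0) 0 else mean(l)
  } else l
}

# d FL / d logit, used by the trainer (logit z with p = sigmoid(z)).
# y = 1: alpha * (1-p)^gamma * (gamma * p * log(p) - (1 - p))
# y = 0: alpha * p^gamma * (p - gamma * (1 - p) * log(1 - p))
focal_grad_logit <- function(p, y, alpha = 16, gamma = 2, eps = 1e-7) {
  p <- clip(p, eps, 1 - eps)
  ifelse(y == 1,
         alpha * (1 - p)^gamma * (gamma * p * log(p) - (1 - p)),
         alpha * p^gamma * (p - gamma * (1 - p) * log(1 - p)))
}

#' Confidence-gated consistency loss
#'
#' Implements the unlabeled-stream term of the objective: for each sample,
#' the confidence of the weak-view prediction is `max(p, 1 - p)`; when it
#' reaches `tau_c` the sample is gated in, given the hard label
#' `[p_weak >= 0.5]`, and contributes the focal loss of the strong-view
#' prediction against that label. `lu` is the mean over gated samples and
#' exactly 0 when none pass. Gradients are meant to flow through the strong
#' view only; the weak scores act as fixed targets.
#'
#' @param weak_scores,strong_scores Equal-length score vectors from the two
#'   augmented views.
#' @param tau_c Confidence threshold.
#' @param alpha,gamma Focal parameters.
#' @return A list with `lu`, the logical `gate_mask`, and the hard
#'   `pseudo_targets` (NA where not gated).
#' @export
consistency_loss <- function(weak_scores, strong_scores, tau_c = 0.95,
                             alpha = 16, gamma = 2) {
  stopifnot(length(weak_scores) == length(strong_scores))
  conf <- pmax(weak_scores, 1 - weak_scores)
  gate <- conf >= tau_c
  targets <- ifelse(gate, as.numeric(weak_scores >= 0.5), NA_real_)
  lu <- if (any(gate)) {
    focal_loss(strong_scores[gate], targets[gate], alpha, gamma)
  } else 0
  list(lu = lu, gate_mask = gate, pseudo_targets = targets)
}

#' Assign pseudo-labels from a teacher's scores
#'
#' Scores at or below `lo` become negative, at or above `hi` positive,
#' anything in between abstains. In the training pipeline the teacher is a
#' network fully trained on phantom data alone, applied once to the
#' unlabeled stream before semi-supervised training starts.
#'
#' @param teacher_scores Numeric scores in `[0, 1]`.
#' @param lo,hi Thresholds (defaults 0.01 and 0.99).
#' @return A factor with levels `negative`, `abstain`, `positive`.
#' @export
assign_pseudo_labels <- function(teacher_scores, lo = 0.01, hi = 0.99) {
  stopifnot(all(teacher_scores >= 0 & teacher_scores <= 1), lo < hi)
  out <- ifelse(teacher_scores <= lo, "negative",
                ifelse(teacher_scores >= hi, "positive", "abstain"))
  factor(out, levels = c("negative", "abstain", "positive"))
}

#' Combine the three loss terms
#'
#' @param ls,lu,lp Term values (finite, non-negative).
#' @param lambda1,lambda2 Weights of `lu` and `lp`.
#' @return `ls + lambda1 * lu + lambda2 * lp`.
#' @export
combined_loss <- function(ls, lu, lp, lambda1 = 0.5, lambda2 = 0.5) {
  stopifnot(is.finite(ls), is.finite(lu), is.finite(lp))
  ls + lambda1 * lu + lambda2 * lp
}

#' Train the FP-reduction network
#'
#' The semi-supervised training loop. Each step draws a labeled batch
#' (passed through the labeled augmentation policy) and, when unlabeled data
#' are present, an unlabeled batch rendered in a weak and a strong view.
#' The parameters are updated by Adam on
#' `L = ls + lambda1 * lu + lambda2 * lp` plus weight decay on the
#' convolution kernels. With no unlabeled data the loop reduces exactly to
#' supervised focal-loss training (`lu = lp = 0`). Deterministic given
#' `seed`.
#'
#' @param labeled A tibble with `patch` (list of 3D arrays) and `label`
#'   (`"positive"`/`"negative"` or 0/1) columns; must be non-empty.
#' @param unlabeled Optional tibble with a `patch` column. If a `teacher`
#'   is supplied, pseudo-labels are assigned from its scores before
#'   training; an existing `pseudo_label` column is used as-is.
#' @param net_config A [network_config()].
#' @param loss_cfg A [loss_config()].
#' @param epochs,steps_per_epoch,batch_labeled,batch_unlabeled Loop sizes.
#' @param lr Adam learning rate (decayed to zero on a cosine schedule
#'   when `lr_decay` is `TRUE`).
#' @param lr_decay Apply cosine learning-rate decay over the run.
#' @param average_tail Fraction of final training steps whose parameters
#'   are averaged into the returned network (0 disables; tail averaging
#'   damps end-of-run stochasticity of small-batch training).
#' @param seed Integer master seed for initialization, batching, dropout
#'   and augmentation.
#' @param teacher Optional `fpr_net` used to score `unlabeled` for
#'   pseudo-labels (typically a phantom-only supervised checkpoint).
#' @param policies Named list of [augment_policy()] objects for the
#'   `labeled`, `weak` and `strong` streams.
#' @return An `fpr_fit`: list with `net` (the trained `fpr_net`), `history`
#'   (a tibble with one row per epoch: `epoch, ls, lu, lp, loss,
#'   gate_fraction`), and the configurations.
#' @export
train_fpr <- function(labeled, unlabeled = NULL,
                      net_config = network_config(),
                      loss_cfg = loss_config(),
                      epochs = 10, steps_per_epoch = 10,
                      batch_labeled = 16, batch_unlabeled = 16,
                      lr = 1e-3, lr_decay = FALSE, average_tail = 0,
                      seed = 1L, teacher = NULL,
                      policies = list(labeled = augment_policy("labeled"),
                                      weak = augment_policy("weak"),
                                      strong = augment_policy("strong"))) {
  stopifnot(nrow(labeled) > 0)
  y_lab <- as_binary_label(labeled$label)
  have_unlab <- !is.null(unlabeled) && nrow(unlabeled) > 0
  pseudo <- NULL
  if (have_unlab) {
    if (!is.null(teacher)) {
      tsc <- predict(teacher, unlabeled$patch)
      pseudo <- assign_pseudo_labels(tsc, loss_cfg$pseudo_lo,
                                     loss_cfg$pseudo_hi)
    } else if ("pseudo_label" %in% names(unlabeled)) {
      pseudo <- factor(unlabeled$pseudo_label,
                       levels = c("negative", "abstain", "positive"))
    } else {
      pseudo <- factor(rep("abstain", nrow(unlabeled)),
                       levels = c("negative", "abstain", "positive"))
    }
  }

  {
    # RNG discipline: every stochastic ingredient draws from its own seed
    # stream derived from (seed, step). Runs with a shared seed therefore
    # share initialization, batch sequences and dropout masks even when
    # their augmentation policies or data streams differ — common random
    # numbers across experiment arms.
    net <- build_network(net_config, seed = child_seed(seed, 1L))
    flat <- flatten_params(net$params)
    opt_state <- NULL
    decay_mask <- weight_decay_mask(net)
    history <- vector("list", epochs)
    total_steps <- epochs * steps_per_epoch
    tail_sum <- numeric(length(flat))
    tail_n <- 0L
    for (ep in seq_len(epochs)) {
      ep_ls <- ep_lu <- ep_lp <- ep_L <- ep_gate <- numeric(steps_per_epoch)
      for (st in seq_len(steps_per_epoch)) {
        t_id <- (ep - 1L) * steps_per_epoch + st
        st_seed <- function(k) child_seed(child_seed(seed, 1000L + t_id), k)
        ## assemble the step batch: labeled view plus, when present, the
        ## weak and strong views of the unlabeled batch. All views share
        ## one forward/backward pass; the per-view loss gradients land in
        ## the corresponding slots of a single dL/dlogit vector.
        li <- with_seed(st_seed(1L),
                        sample.int(nrow(labeled), batch_labeled,
                                   replace = TRUE))
        lab_patches <- lapply(seq_along(li), function(j)
          apply_augment(labeled$patch[[li[j]]], policies$labeled,
                        seed = child_seed(st_seed(2L), j)))
        yl <- y_lab[li]
        patches <- lab_patches
        ui <- integer(0)
        if (have_unlab) {
          ui <- with_seed(st_seed(4L),
                          sample.int(nrow(unlabeled), batch_unlabeled,
                                     replace = TRUE))
          weak_p <- lapply(seq_along(ui), function(j)
            apply_augment(unlabeled$patch[[ui[j]]], policies$weak,
                          seed = child_seed(st_seed(5L), j)))
          strong_p <- lapply(seq_along(ui), function(j)
            apply_augment(unlabeled$patch[[ui[j]]], policies$strong,
                          seed = child_seed(st_seed(6L), j)))
          patches <- c(patches, weak_p, strong_p)
        }
        fwd <- with_seed(st_seed(3L),
                         net_forward(net, patches, training = TRUE))
        nl <- length(li); nu <- length(ui)
        sc_l <- fwd$scores[seq_len(nl)]
        ls <- focal_loss(sc_l, yl, loss_cfg$focal_alpha,
                         loss_cfg$focal_gamma)
        glog <- numeric(length(patches))
        glog[seq_len(nl)] <- focal_grad_logit(sc_l, yl,
                                              loss_cfg$focal_alpha,
                                              loss_cfg$focal_gamma) / nl

        lu <- lp <- 0
        gate_frac <- 0
        if (have_unlab) {
          iw <- nl + seq_len(nu)
          is <- nl + nu + seq_len(nu)
          sc_w <- fwd$scores[iw]
          sc_s <- fwd$scores[is]
          cons <- consistency_loss(sc_w, sc_s, loss_cfg$tau_c,
                                   loss_cfg$focal_alpha,
                                   loss_cfg$focal_gamma)
          lu <- cons$lu
          gate_frac <- mean(cons$gate_mask)
          if (any(cons$gate_mask)) {
            # consistency gradients flow through the strong view only
            glog[is[cons$gate_mask]] <- glog[is[cons$gate_mask]] +
              loss_cfg$lambda1 * focal_grad_logit(
                sc_s[cons$gate_mask], cons$pseudo_targets[cons$gate_mask],
                loss_cfg$focal_alpha, loss_cfg$focal_gamma) /
              sum(cons$gate_mask)
          }
          pl <- pseudo[ui]
          use <- pl != "abstain"
          if (any(use)) {
            yp <- as.numeric(pl[use] == "positive")
            lp <- focal_loss(sc_w[use], yp, loss_cfg$focal_alpha,
                             loss_cfg$focal_gamma)
            glog[iw[use]] <- glog[iw[use]] +
              loss_cfg$lambda2 * focal_grad_logit(
                sc_w[use], yp, loss_cfg$focal_alpha,
                loss_cfg$focal_gamma) / sum(use)
          }
        }
        grad <- flatten_params(net_backward(net, fwd, glog))

        if (loss_cfg$weight_decay > 0) {
          grad <- grad + loss_cfg$weight_decay * decay_mask * flat
        }
        L <- combined_loss(ls, lu, lp, loss_cfg$lambda1, loss_cfg$lambda2)
        if (!is.finite(L)) {
          stop("training diverged at epoch ", ep, " step ", st,
               " (loss = ", L, ")", call. = FALSE)
        }
        lr_t <- if (lr_decay) {
          lr * 0.5 * (1 + cos(pi * (t_id - 1) / total_steps))
        } else lr
        upd <- adam_step(flat, grad, opt_state, lr = lr_t)
        flat <- upd$flat
        opt_state <- upd$state
        net$params <- assign_flat(net$params, flat)
        if (average_tail > 0 && t_id > (1 - average_tail) * total_steps) {
          tail_sum <- tail_sum + flat
          tail_n <- tail_n + 1L
        }
        ep_ls[st] <- ls; ep_lu[st] <- lu; ep_lp[st] <- lp
        ep_L[st] <- L; ep_gate[st] <- gate_frac
      }
      history[[ep]] <- tibble::tibble(
        epoch = ep, ls = mean(ep_ls), lu = mean(ep_lu), lp = mean(ep_lp),
        loss = mean(ep_L), gate_fraction = mean(ep_gate)
      )
    }
    if (tail_n > 0) {
      net$params <- assign_flat(net$params, tail_sum / tail_n)
    }
    structure(
      list(net = net, history = dplyr::bind_rows(history),
           loss_cfg = loss_cfg, net_config = net_config, seed = seed),
      class = "fpr_fit"
    )
  }
}

weight_decay_mask <- function(net) {
  # decay applies to convolution kernel weights only
  mask <- lapply(net$params$conv, function(p)
    list(W = array(1, dim(p$W)), b = numeric(length(p$b))))
  zeros <- lapply(net$params$fc, function(p)
    list(W = array(0, dim(p$W)), b = numeric(length(p$b))))
  flatten_params(list(conv = mask, fc = zeros,
                      head = list(w = numeric(length(net$params$head$w)),
                                  b = 0)))
}

as_binary_label <- function(label) {
  if (is.numeric(label)) {
    stopifnot(all(label %in% c(0, 1)))
    as.numeric(label)
  } else {
    as.numeric(as.character(label) == "positive")
  }
}

#' @export
print.fpr_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<fpr_fit> %d epochs | final ls=%.4g lu=%.4g lp=%.4g L=%.4g gate=%.2f\n",
    nrow(x$history), last$ls, last$lu, last$lp, last$loss,
    last$gate_fraction))
  invisible(x)
}

#' @export
predict.fpr_fit <- function(object, patches, ...) {
  predict(object$net, patches, ...)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#'
#' @param x An `fpr_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble in long form: `epoch`, `term`
#'   (`ls`/`lu`/`lp`/`loss`), `value`, plus `gate_fraction` kept wide.
#' @method tidy fpr_fit
#' @export
tidy.fpr_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, cols = c("ls", "lu", "lp", "loss"),
                      names_to = "term", values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x An `fpr_fit`.
#' @param ... Unused.
#' @return A tibble with the final-epoch loss terms, the gate fraction and
#'   the parameter count.
#' @method glance fpr_fit
#' @export
glance.fpr_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history), ls = last$ls, lu = last$lu, lp = last$lp,
    loss = last$loss, gate_fraction = last$gate_fraction,
    n_parameters = n_parameters(x$net)
  )
}

#' Plot training history
#'
#' @param object An `fpr_fit`.
#' @param ... Unused.
#' @return A ggplot of the loss terms over epochs.
#' @method autoplot fpr_fit
#' @export
autoplot.fpr_fit <- function(object, ...) {
  df <- tidy.fpr_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = "term") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
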
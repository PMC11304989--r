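#' Match scored candidates against reference nodules
#'
#' Applies the hit criterion: a candidate is a true positive when its centre
#' lies within `diameter / 2` of a truth centre on the same scan (the
#' annotation's bounding sphere stands in for the lesion boundary). Several
#' candidates may hit one truth, but each truth counts as detected only
#' once when the curve is swept. Candidates whose only hits are on ignored
#' findings (see [filter_test_truths()]) are flagged and count as neither
#' true nor false positives.
#'
#' @param candidates Tibble with `seriesuid`, `coordX/Y/Z` and `score`.
#' @param truths Considered annotation tibble (`seriesuid`, `coordX/Y/Z`,
#'   `diameter_mm`).
#' @param ignore Optional annotation tibble of excluded findings.
#' @return The candidate tibble with columns `hit_truth` (index into
#'   `truths`, NA for misses), `is_tp` and `ignored`.
#' @export
match_detections <- function(candidates, truths, ignore = NULL) {
  n <- nrow(candidates)
  hit_idx <- rep(NA_integer_, n)
  best_d2 <- rep(Inf, n)
  if (nrow(truths) > 0 && n > 0) {
    for (i in seq_len(nrow(truths))) {
      same <- candidates$seriesuid == truths$seriesuid[i]
      d2 <- (candidates$coordX - truths$coordX[i])^2 +
        (candidates$coordY - truths$coordY[i])^2 +
        (candidates$coordZ - truths$coordZ[i])^2
      inside <- same & d2 <= (truths$diameter_mm[i] / 2)^2
      take <- inside & d2 < best_d2
      hit_idx[take] <- i
      best_d2[take] <- d2[take]
    }
  }
  ignored <- rep(FALSE, n)
  if (!is.null(ignore) && nrow(ignore) > 0 && n > 0) {
    # a candidate is ignored when it hits an excluded finding and no
    # considered truth
    hits_ignored <- rep(FALSE, n)
    for (i in seq_len(nrow(ignore))) {
      same <- candidates$seriesuid == ignore$seriesuid[i]
      d2 <- (candidates$coordX - ignore$coordX[i])^2 +
        (candidates$coordY - ignore$coordY[i])^2 +
        (candidates$coordZ - ignore$coordZ[i])^2
      hits_ignored <- hits_ignored |
        (same & d2 <= (ignore$diameter_mm[i] / 2)^2)
    }
    ignored <- hits_ignored & is.na(hit_idx)
  }
  out <- candidates
  out$hit_truth <- hit_idx
  out$is_tp <- !is.na(hit_idx)
  out$ignored <- ignored
  out
}

#' Free-response ROC curve
#'
#' Sweeps the score threshold over all unique candidate scores and records,
#' at each, the sensitivity (detected truths / total truths, a truth
#' counting once however many candidates hit it) and the false-positive
#' rate per scan. Ignored candidates contribute to neither count.
#' Sensitivity at an arbitrary rate is obtained by linear interpolation on
#' the FP axis (step-hold below the lowest achieved rate, configurable to a
#' step function).
#'
#' @param detections Output of [match_detections()] with a `score` column.
#' @param n_scans Number of scans in the evaluated population (>= 1).
#' @param n_truths Total number of considered truths; defaults to the
#'   number of distinct `hit_truth` values plus undetected truths cannot be
#'   inferred, so pass it explicitly whenever some truths receive no
#'   candidate.
#' @return An object of class `froc_result` with the operating-point tibble
#'   (`threshold`, `fp_per_scan`, `sensitivity`), `n_scans` and `n_truths`.
#' @export
froc_curve <- function(detections, n_scans, n_truths = NULL) {
  stopifnot(n_scans >= 1)
  det <- detections[!detections$ignored, , drop = FALSE]
  if (is.null(n_truths)) {
    n_truths <- length(unique(stats::na.omit(det$hit_truth)))
  }
  if (n_truths == 0) {
    stop("zero truths: sensitivity undefined", call. = FALSE)
  }
  ord <- order(det$score, decreasing = TRUE)
  det <- det[ord, , drop = FALSE]
  # at threshold t: candidates with score >= t are called positive
  thr <- sort(unique(det$score), decreasing = TRUE)
  is_fp <- !det$is_tp
  cum_fp <- cumsum(is_fp)
  # first detection of each truth (by the sweep order)
  first_hit <- !is.na(det$hit_truth) & !duplicated(det$hit_truth,
                                                   incomparables = NA)
  cum_tp_truths <- cumsum(first_hit)
  pos_at_thr <- findInterval(-thr, -det$score)  # candidates with score >= thr
  points <- tibble::tibble(
    threshold = thr,
    fp_per_scan = cum_fp[pos_at_thr] / n_scans,
    sensitivity = cum_tp_truths[pos_at_thr] / n_truths
  )
  structure(
    list(points = points, n_scans = n_scans, n_truths = n_truths),
    class = "froc_result"
  )
}

#' @export
print.froc_result <- function(x, ...) {
  cat(sprintf("<froc_result> %d scans, %d truths, %d operating points\n",
              x$n_scans, x$n_truths, nrow(x$points)))
  s <- sensitivity_at(x, cpm_rates())
  cat("  sensitivity @ {", paste(cpm_rates(), collapse = ", "),
      "} FP/scan:\n  ", paste(sprintf("%.3f", s), collapse = "  "),
      "\n  CPM:", sprintf("%.3f", mean(s)), "\n")
  invisible(x)
}

#' The seven CPM operating rates
#'
#' @return `c(0.125, 0.25, 0.5, 1, 2, 4, 8)` false positives per scan.
#' @export
cpm_rates <- function() c(0.125, 0.25, 0.5, 1, 2, 4, 8)

#' Sensitivity at given FP rates
#'
#' @param froc A `froc_result`.
#' @param rates FP-per-scan rates.
#' @param interpolation `"linear"` (default) interpolates sensitivity
#'   linearly between achieved FP rates; `"step"` holds the last achieved
#'   value.
#' @details At a tied FP rate the curve takes the best achievable
#'   sensitivity (right-continuous, the convention of `np.interp`-style
#'   evaluators). Below the lowest achieved rate that point's sensitivity
#'   is held down to rate 0; above the largest achieved rate the final
#'   sensitivity is held.
#' @return Numeric vector of sensitivities.
#' @export
sensitivity_at <- function(froc, rates = cpm_rates(),
                           interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  pts <- froc$points
  # points arrive in threshold-descending order, so fp and sensitivity are
  # both non-decreasing; the best sensitivity at each achieved fp rate is
  # the last entry of its run
  fp_all <- pts$fp_per_scan
  keep <- c(fp_all[-1] != fp_all[-length(fp_all)], TRUE)
  fp <- fp_all[keep]
  se <- pts$sensitivity[keep]
  if (fp[1] > 0) {  # step-hold below the lowest achieved rate
    fp <- c(0, fp)
    se <- c(se[1], se)
  }
  if (interpolation == "linear") {
    stats::approx(fp, se, xout = pmin(rates, max(fp)), ties = "ordered",
                  rule = 2)$y
  } else {
    se[findInterval(pmin(rates, max(fp)), fp)]
  }
}

#' Competition performance metric
#'
#' The arithmetic mean of the sensitivities at 0.125, 0.25, 0.5, 1, 2, 4
#' and 8 false positives per scan.
#'
#' @param x A `froc_result`, or directly a numeric vector of the seven
#'   sensitivities.
#' @param ... Passed to [sensitivity_at()] for `froc_result` input.
#' @return The CPM in `[0, 1]`.
#' @export
#' @examples
#' cpm(c(0.468, 0.557, 0.623, 0.662, 0.717, 0.756, 0.789))  # 0.653
cpm <- function(x, ...) UseMethod("cpm")

#' @export
cpm.froc_result <- function(x, ...) mean(sensitivity_at(x, cpm_rates(), ...))

#' @export
cpm.numeric <- function(x, ...) {
  stopifnot(length(x) == 7L, all(x >= 0 & x <= 1))
  mean(x)
}

#' Tidy FROC operating points
#'
#' @param x A `froc_result`.
#' @param ... Unused.
#' @return The operating-point tibble.
#' @method tidy froc_result
#' @export
tidy.froc_result <- function(x, ...) x$points

#' One-row FROC summary
#'
#' @param x A `froc_result`.
#' @param ... Unused.
#' @return Tibble with `cpm`, the seven rate sensitivities, `n_scans`,
#'   `n_truths`.
#' @method glance froc_result
#' @export
glance.froc_result <- function(x, ...) {
  s <- sensitivity_at(x)
  out <- tibble::tibble(cpm = mean(s), n_scans = x$n_scans,
                        n_truths = x$n_truths)
  names(s) <- paste0("sens_fp", cpm_rates())
  dplyr::bind_cols(out, tibble::as_tibble(as.list(s)))
}

#' Plot an FROC curve
#'
#' @param object A `froc_result`.
#' @param ... Unused.
#' @return A ggplot with a log-scaled FP axis and the seven CPM rates
#'   marked.
#' @method autoplot froc_result
#' @export
autoplot.froc_result <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fp_per_scan,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_vline(xintercept = cpm_rates(), linetype = 3,
                        colour = "grey60") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::coord_cartesian(xlim = c(0.125, 8), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positives per scan", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Bootstrap confidence interval of a CPM difference
#'
#' Resamples scans with replacement `n_boot` times; for each replicate both
#' detection sets are re-scored on the resampled scan population and the
#' difference `CPM(A) - CPM(B)` recorded. The interval is the 2.5/97.5
#' percentile of the replicate differences.
#'
#' @param det_a,det_b Matched detection tibbles (from [match_detections()])
#'   for the two systems, scored on the same scan population.
#' @param truths Considered truth tibble for that population.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A list with `ci` (length-2 numeric), `diff` (observed
#'   difference) and the replicate vector `boot_diffs`.
#' @export
bootstrap_cpm_diff <- function(det_a, det_b, truths, n_boot = 1000,
                               seed = 1L, conf = 0.95) {
  scans <- unique(c(det_a$seriesuid, det_b$seriesuid, truths$seriesuid))
  if (length(scans) < 2) {
    stop("bootstrap needs at least 2 scans", call. = FALSE)
  }
  # pre-split per scan into plain vectors: each replicate reassembles by
  # concatenation, the cheapest route at 1000 replicates
  split_by <- function(det) {
    keep <- !det$ignored
    lapply(stats::setNames(scans, scans), function(s) {
      sel <- keep & det$seriesuid == s
      list(score = det$score[sel], is_tp = det$is_tp[sel],
           hit = det$hit_truth[sel])
    })
  }
  parts_a <- split_by(det_a)
  parts_b <- split_by(det_b)
  truths_per_scan <- vapply(scans, function(s)
    sum(truths$seriesuid == s), integer(1))
  cpm_on <- function(parts, ids) {
    n_truths <- sum(truths_per_scan[ids])
    if (n_truths == 0) return(NA_real_)
    px <- parts[ids]
    lens <- vapply(px, function(p) length(p$score), integer(1))
    # re-key truth ids so repeated copies of a scan count separately
    copy <- rep(seq_along(ids), lens)
    det <- tibble::tibble(
      score = unlist(lapply(px, `[[`, "score"), use.names = FALSE),
      is_tp = unlist(lapply(px, `[[`, "is_tp"), use.names = FALSE),
      hit_truth = paste0(copy, "_",
                         unlist(lapply(px, `[[`, "hit"),
                                use.names = FALSE)),
      ignored = FALSE
    )
    det$hit_truth[!det$is_tp] <- NA_character_
    cpm(froc_curve(det, n_scans = length(ids), n_truths = n_truths))
  }
  with_seed(seed, {
    diffs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      ids <- sample(scans, length(scans), replace = TRUE)
      diffs[b] <- cpm_on(parts_a, ids) - cpm_on(parts_b, ids)
    }
    diffs <- diffs[is.finite(diffs)]
    alpha <- (1 - conf) / 2
    obs <- cpm_on(parts_a, scans) - cpm_on(parts_b, scans)
    list(ci = unname(stats::quantile(diffs, c(alpha, 1 - alpha))),
         diff = obs, boot_diffs = diffs)
  })
}

#' Random-prediction baseline
#'
#' Assigns each candidate an independent uniform(0, 1) confidence score,
#' the reference "no information" system for FROC comparisons.
#'
#' @param candidates Candidate tibble.
#' @param seed Integer seed.
#' @return The tibble with a fresh `score` column.
#' @export
random_baseline <- function(candidates, seed = 1L) {
  with_seed(seed, {
    candidates$score <- stats::runif(nrow(candidates))
    candidates
  })
}

#' Split annotations into considered truths and an ignore list
#'
#' Applies the reference-standard filter: findings are considered when
#' their diameter exceeds `min_diameter_mm` and at least `min_agreement` of
#' the four annotators marked them. Everything else goes to the ignore
#' list: hits on those findings count as neither true nor false positives.
#'
#' @param annotations Annotation tibble with `diameter_mm` and `agreement`
#'   columns (`agreement` defaults to 4 when absent).
#' @param min_diameter_mm Diameter threshold (strict, default 3 mm).
#' @param min_agreement Reader-agreement threshold (default 3).
#' @return A list with tibbles `considered` and `ignored`.
#' @export
filter_test_truths <- function(annotations, min_diameter_mm = 3,
                               min_agreement = 3) {
  agree <- if ("agreement" %in% names(annotations)) {
    annotations$agreement
  } else rep(4L, nrow(annotations))
  keep <- annotations$diameter_mm > min_diameter_mm & agree >= min_agreement
  list(considered = annotations[keep, , drop = FALSE],
       ignored = annotations[!keep, , drop = FALSE])
}
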
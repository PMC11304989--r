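toy_detections <- function() {
  # 2 scans, truths A (scan s1) and B (s2); candidates as (score, type)
  truths <- tibble::tibble(
    seriesuid = c("s1", "s2"),
    coordX = c(0, 0), coordY = c(0, 0), coordZ = c(0, 0),
    diameter_mm = c(10, 10)
  )
  cand <- tibble::tibble(
    seriesuid = c("s1", "s1", "s2", "s2"),
    coordX = c(1, 40, 2, 50), coordY = 0, coordZ = 0,
    score = c(0.9, 0.8, 0.7, 0.6)
  )
  list(truths = truths, cand = cand)
}

test_that("the hit criterion uses the truth bounding sphere", {
  truths <- tibble::tibble(seriesuid = "s", coordX = 0, coordY = 0,
                           coordZ = 0, diameter_mm = 10)
  cand <- tibble::tibble(
    seriesuid = "s",
    coordX = c(4.5, 5.5, 0), coordY = 0, coordZ = 0,   # 0.9 r, 1.1 r, centre
    score = c(0.5, 0.5, 0.5)
  )
  det <- match_detections(cand, truths)
  expect_equal(det$is_tp, c(TRUE, FALSE, TRUE))
})

test_that("multiple hits on one truth count it detected once", {
  truths <- tibble::tibble(seriesuid = "s", coordX = 0, coordY = 0,
                           coordZ = 0, diameter_mm = 10)
  cand <- tibble::tibble(
    seriesuid = "s", coordX = c(1, -1, 30), coordY = 0, coordZ = 0,
    score = c(0.9, 0.8, 0.7)
  )
  det <- match_detections(cand, truths)
  froc <- froc_curve(det, n_scans = 1, n_truths = 1)
  # at the loosest threshold: 1 detected truth, 1 FP (the miss at x = 30)
  last <- froc$points[nrow(froc$points), ]
  expect_equal(last$sensitivity, 1)
  expect_equal(last$fp_per_scan, 1)
})

test_that("matching is independent of candidate ordering", {
  toy <- toy_detections()
  det1 <- match_detections(toy$cand, toy$truths)
  perm <- c(3, 1, 4, 2)
  det2 <- match_detections(toy$cand[perm, ], toy$truths)
  expect_equal(det2$is_tp, det1$is_tp[perm])
})

test_that("the toy FROC reproduces hand-computed operating points", {
  toy <- toy_detections()
  det <- match_detections(toy$cand, toy$truths)
  froc <- froc_curve(det, n_scans = 2, n_truths = 2)
  # threshold enumeration: 0.9 -> (0, 0.5); 0.8 -> (0.5, 0.5);
  # 0.7 -> (0.5, 1.0); 0.6 -> (1, 1). At a tied FP rate the curve takes
  # the best achievable sensitivity (right-continuous, as np.interp-style
  # evaluators do), so 0.5 FP/scan already buys both truths here.
  expect_equal(sensitivity_at(froc, 0), 0.5)
  expect_equal(sensitivity_at(froc, 0.5), 1.0)
  expect_equal(sensitivity_at(froc, 1.0), 1.0)
  # linear interpolation between achieved rates vs step-hold
  expect_equal(sensitivity_at(froc, 0.25), 0.75)
  expect_equal(sensitivity_at(froc, 0.25, interpolation = "step"), 0.5)
})

test_that("the curve agrees with the brute-force threshold enumeration", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    n_truths <- sample(1:4, 1)
    truth_of <- sample(c(rep(NA, n - min(n, n_truths)),
                         seq_len(min(n, n_truths))))
    scores <- round(runif(n), 2)  # ties exercised by rounding
    det <- tibble::tibble(
      seriesuid = "s", score = scores,
      is_tp = !is.na(truth_of), hit_truth = truth_of,
      ignored = FALSE
    )
    froc <- froc_curve(det, n_scans = 2, n_truths = n_truths)
    oracle <- brute_force_froc(scores, det$is_tp, truth_of, 2, n_truths)
    got <- as.matrix(froc$points[, c("threshold", "fp_per_scan",
                                     "sensitivity")])
    expect_equal(got, oracle[order(-oracle[, "threshold"]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("FROC sensitivity is monotone in the FP rate", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 50
    det <- tibble::tibble(
      seriesuid = sample(c("a", "b", "c"), n, replace = TRUE),
      score = runif(n),
      is_tp = runif(n) < 0.3,
      ignored = FALSE
    )
    det$hit_truth <- ifelse(det$is_tp, seq_len(n), NA_integer_)
    froc <- froc_curve(det, n_scans = 3, n_truths = sum(det$is_tp) + 2)
    pts <- dplyr::arrange(froc$points, fp_per_scan)
    expect_true(all(diff(pts$sensitivity) >= -1e-12))
    s <- sensitivity_at(froc)
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("perfect and useless scorers hit the sensitivity extremes", {
  truths <- tibble::tibble(seriesuid = "s", coordX = 0, coordY = 0,
                           coordZ = 0, diameter_mm = 10)
  cand <- tibble::tibble(
    seriesuid = "s", coordX = c(0, 30, 40), coordY = 0, coordZ = 0,
    score = c(0.99, 0.1, 0.05)
  )
  det <- match_detections(cand, truths)
  froc <- froc_curve(det, n_scans = 1, n_truths = 1)
  expect_true(all(sensitivity_at(froc, c(0, 0.5, 1, 8)) == 1))

  all_fp <- tibble::tibble(
    seriesuid = "s", coordX = c(30, 40), coordY = 0, coordZ = 0,
    score = c(0.8, 0.6)
  )
  det2 <- match_detections(all_fp, truths)
  froc2 <- froc_curve(det2, n_scans = 1, n_truths = 1)
  expect_true(all(sensitivity_at(froc2) == 0))
  expect_error(froc_curve(det2, n_scans = 1, n_truths = 0), "zero truths")
})

test_that("cpm averages the seven printed sensitivities", {
  expect_lt(abs(cpm(c(0.468, 0.557, 0.623, 0.662, 0.717, 0.756, 0.789)) -
                  0.653), 5e-4)
  expect_equal(cpm(rep(1, 7)), 1)
  expect_lt(abs(cpm(c(0.578, 0.668, 0.726, 0.778, 0.814, 0.853, 0.875)) -
                  0.756), 5e-4)
  expect_error(cpm(c(0.5, 0.6)))
})

test_that("identical systems bootstrap to a degenerate [0, 0] interval", {
  pair <- simulate_detection_pair(n_scans = 8, sens_a = 0.7, sens_b = 0.7,
                                  seed = 3)
  ci <- bootstrap_cpm_diff(pair$det_a, pair$det_a, pair$truths,
                           n_boot = 50, seed = 4)
  expect_equal(ci$ci, c(0, 0))
  expect_equal(ci$diff, 0)
  # and intervals are always ordered
  ci2 <- bootstrap_cpm_diff(pair$det_a, pair$det_b, pair$truths,
                            n_boot = 50, seed = 5)
  expect_lte(ci2$ci[1], ci2$ci[2])
  expect_error(bootstrap_cpm_diff(pair$det_a[pair$det_a$seriesuid == "s001", ],
                                  pair$det_a[pair$det_a$seriesuid == "s001", ],
                                  pair$truths[pair$truths$seriesuid == "s001", ]),
               "2 scans")
})

test_that("the random baseline matches its analytic sensitivity", {
  # N uniform-scored negatives per scan: P(truth outranks all but f N) at
  # rate f FP/scan is f / N
  set.seed(7)
  n_scans <- 100
  N <- 750
  truths <- tibble::tibble(
    seriesuid = sprintf("s%03d", seq_len(n_scans)),
    coordX = 0, coordY = 0, coordZ = 0, diameter_mm = 10
  )
  cand <- dplyr::bind_rows(lapply(seq_len(n_scans), function(i) {
    tibble::tibble(
      seriesuid = sprintf("s%03d", i),
      coordX = c(0, seq(30, length.out = N, by = 5)),
      coordY = 0, coordZ = 0
    )
  }))
  scored <- random_baseline(cand, seed = 8)
  expect_true(all(scored$score >= 0 & scored$score <= 1))
  expect_identical(random_baseline(cand, seed = 8)$score, scored$score)
  det <- match_detections(scored, truths)
  froc <- froc_curve(det, n_scans = n_scans, n_truths = n_scans)
  for (f in c(2, 4, 8)) {
    expected <- f / N
    se <- sqrt(expected * (1 - expected) / n_scans)
    expect_lt(abs(sensitivity_at(froc, f) - expected), 3 * se + 1e-9)
  }
})

test_that("excluded findings are ignored by the matcher", {
  ann <- tibble::tibble(
    seriesuid = "s",
    coordX = c(0, 50, 100), coordY = 0, coordZ = 0,
    diameter_mm = c(10, 2.5, 8),
    agreement = c(4L, 4L, 2L)
  )
  split <- filter_test_truths(ann)
  expect_equal(nrow(split$considered), 1L)
  expect_equal(nrow(split$ignored), 2L)
  expect_true(all(split$ignored$coordX == c(50, 100)))

  cand <- tibble::tibble(
    seriesuid = "s", coordX = c(0, 50, 200), coordY = 0, coordZ = 0,
    score = c(0.9, 0.8, 0.7)
  )
  det <- match_detections(cand, split$considered, ignore = split$ignored)
  expect_equal(det$is_tp, c(TRUE, FALSE, FALSE))
  expect_equal(det$ignored, c(FALSE, TRUE, FALSE))
  froc <- froc_curve(det, n_scans = 1, n_truths = 1)
  # the candidate on the ignored finding contributes no FP: at the loosest
  # threshold there is exactly 1 FP (the stray at x = 200)
  expect_equal(max(froc$points$fp_per_scan), 1)
  # re-run without the ignore list: now 2 FPs
  det2 <- match_detections(cand, split$considered)
  froc2 <- froc_curve(det2, n_scans = 1, n_truths = 1)
  expect_equal(max(froc2$points$fp_per_scan), 2)
})

test_that("bootstrap intervals cover a known sensitivity gap", {
  # small-scale coverage check; the acceptance suite runs the full version
  hits <- vapply(1:20, function(r) {
    pair <- simulate_detection_pair(n_scans = 25, truths_per_scan = 4,
                                    sens_a = 0.8, sens_b = 0.6,
                                    seed = 100 + r)
    ci <- bootstrap_cpm_diff(pair$det_a, pair$det_b, pair$truths,
                             n_boot = 100, seed = r)
    ci$ci[1] <= 0.2 && 0.2 <= ci$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("froc results expose tidy, glance and autoplot", {
  toy <- toy_detections()
  det <- match_detections(toy$cand, toy$truths)
  froc <- froc_curve(det, n_scans = 2, n_truths = 2)
  expect_true(all(c("threshold", "fp_per_scan", "sensitivity") %in%
                    names(tidy(froc))))
  gl <- glance(froc)
  expect_equal(gl$n_scans, 2)
  expect_true("sens_fp8" %in% names(gl))
  expect_s3_class(autoplot(froc), "ggplot")
})
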
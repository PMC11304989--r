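#' Desk-scale benchmark configuration
#'
#' Defines the synthetic study the experiment harness runs: how many
#' phantom, clinical-training and clinical-test scans to simulate, the grid
#' geometry, the candidate budget per scan, the preprocessing target and the
#' (slimmed) network and training sizes. The defaults are sized for a
#' single CPU; every count can be raised for larger studies.
#'
#' @param n_phantom,n_clinical_train,n_test Scan counts per split.
#' @param grid_dim,spacing Simulated scan geometry.
#' @param noise_hu Acquisition noise (HU standard deviation).
#' @param difficulty Clinical-mode mimic richness in `[0, 1]`.
#' @param candidates_per_scan Stage-1 candidate budget per scan.
#' @param proposal_sensitivity Stage-1 recall probability per truth.
#' @param target_spacing Preprocessing target spacing; with `roi_size_mm`
#'   30 the default gives 10 x 16 x 16 patches.
#' @param roi_size_mm ROI cube edge.
#' @param oversample Positive oversampling factor in training sets;
#'   `NULL` (default) balances positives against negatives.
#' @param conv_kernels Kernel counts of the benchmark network (slimmed
#'   relative to the full-scale classifier).
#' @param conv_dropout,fc_dropout Dropout rates for the benchmark network;
#'   lighter than the full-scale defaults because the benchmark net is a
#'   fraction of the size and trains for far fewer steps.
#' @param epochs,steps_per_epoch,batch_labeled,batch_unlabeled,lr Training
#'   loop sizes.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_phantom = 12, n_clinical_train = 12,
                             n_test = 20,
                             grid_dim = c(40, 64, 64),
                             spacing = c(3, 1.875, 1.875),
                             noise_hu = 12, difficulty = 1,
                             candidates_per_scan = 40,
                             proposal_sensitivity = 0.95,
                             target_spacing = c(3, 1.875, 1.875),
                             roi_size_mm = 30, oversample = NULL,
                             conv_kernels = c(4, 8, 16),
                             conv_dropout = 0.1, fc_dropout = 0.5,
                             epochs = 15, steps_per_epoch = 15,
                             batch_labeled = 6, batch_unlabeled = 6,
                             lr = 3e-3) {
  structure(
    list(n_phantom = n_phantom, n_clinical_train = n_clinical_train,
         n_test = n_test, grid_dim = grid_dim, spacing = spacing,
         noise_hu = noise_hu, difficulty = difficulty,
         candidates_per_scan = candidates_per_scan,
         proposal_sensitivity = proposal_sensitivity,
         target_spacing = target_spacing, roi_size_mm = roi_size_mm,
         oversample = oversample, conv_kernels = conv_kernels,
         conv_dropout = conv_dropout, fc_dropout = fc_dropout,
         epochs = epochs, steps_per_epoch = steps_per_epoch,
         batch_labeled = batch_labeled, batch_unlabeled = batch_unlabeled,
         lr = lr),
    class = "benchmark_config"
  )
}

benchmark_net_config <- function(config) {
  network_config(conv_kernels = config$conv_kernels,
                 conv_dropout = config$conv_dropout,
                 fc_dropout = config$fc_dropout,
                 input_shape = as.integer(round(config$roi_size_mm /
                                                  config$target_spacing)))
}

#' Build the synthetic benchmark datasets
#'
#' Simulates the three scan populations (labeled phantom training, unlabeled
#' clinical training, clinical test), runs each scan through the standard
#' preprocessing (resample, clip/rescale), emulates the stage-1 detector,
#' and extracts labeled ROI patches. Training and test scan identifiers are
#' disjoint by construction.
#'
#' @param config A [benchmark_config()].
#' @param seed Master seed.
#' @return A list of three datasets (`phantom`, `clinical_train`, `test`),
#'   each with `rois` (candidate tibble with `patch` and `label`), `truths`
#'   and `n_scans`.
#' @export
build_benchmark <- function(config = benchmark_config(), seed = 1L) {
  phantom <- simulate_split(config, mode = "phantom",
                            n_scans = config$n_phantom,
                            prefix = "bench_phantom",
                            seed = child_seed(seed, 1L))
  clin_tr <- simulate_split(config, mode = "clinical",
                            n_scans = config$n_clinical_train,
                            prefix = "bench_clin_train",
                            seed = child_seed(seed, 2L))
  test <- simulate_split(config, mode = "clinical", n_scans = config$n_test,
                         prefix = "bench_test",
                         seed = child_seed(seed, 3L))
  list(phantom = phantom, clinical_train = clin_tr, test = test)
}

simulate_split <- function(config, mode, n_scans, prefix, seed) {
  rois <- vector("list", n_scans)
  truths <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    sid <- sprintf("%s_%03d", prefix, i)
    scan_seed <- child_seed(seed, i)
    if (mode == "phantom") {
      layout <- with_seed(scan_seed, {
        # the emulated phantom database averages ~7.5 nodules per scan
        # (4254 positive ROIs over 569 layouts); the reduced grid fits 4-7
        nods <- draw_nodules(sample(4:7, 1), config$grid_dim, config$spacing,
                             difficulty = 0)
        scan_layout(sid, nods, grid_dim = config$grid_dim,
                    spacing = config$spacing, noise_hu = config$noise_hu,
                    seed = child_seed(scan_seed, 7L))
      })
      scan <- generate_phantom_scan(layout)
    } else {
      scan <- generate_clinical_scan(
        seed = scan_seed, difficulty = config$difficulty,
        grid_dim = config$grid_dim, spacing = config$spacing,
        noise_hu = config$noise_hu, scan_id = sid)
    }
    cands <- propose_candidates(scan$volume, scan$annotations,
                                n_per_scan = config$candidates_per_scan,
                                sensitivity = config$proposal_sensitivity,
                                seed = child_seed(scan_seed, 11L),
                                scan_id = sid)
    vol <- resample_volume(scan$volume, config$target_spacing)
    vol <- normalize_intensity(vol)
    rois[[i]] <- extract_rois(vol, cands, config$roi_size_mm)
    truths[[i]] <- scan$annotations
  }
  list(rois = dplyr::bind_rows(rois), truths = dplyr::bind_rows(truths),
       n_scans = n_scans)
}

# Augmentation policy sets for the two ablation settings. The basic setting
# uses the traditional flip/translate/rotate trio; the full setting adds
# the heavier parameterized operators.
arm_policies <- function(augmentation = c("basic", "full")) {
  augmentation <- match.arg(augmentation)
  if (augmentation == "full") {
    list(labeled = augment_policy("labeled"),
         weak = augment_policy("weak"),
         strong = augment_policy("strong"))
  } else {
    list(labeled = augment_policy("labeled",
                                  menu = c("flip", "translate", "rotate")),
         weak = augment_policy("weak"),
         strong = augment_policy("strong", menu = c("flip", "translate",
                                                    "rotate")))
  }
}

balance_factor <- function(rois, oversample) {
  if (!is.null(oversample)) return(oversample)
  n_pos <- sum(rois$label == "positive")
  n_neg <- sum(rois$label != "positive")
  if (n_pos == 0) 1L else max(1L, round(n_neg / n_pos))
}

train_arm <- function(benchmark, config, augmentation, use_unlabeled,
                      seed, teacher = NULL, labeled = NULL) {
  if (is.null(labeled)) {
    labeled <- oversample_positives(
      benchmark$phantom$rois,
      factor = balance_factor(benchmark$phantom$rois, config$oversample),
      seed = child_seed(seed, 31L))
  }
  unlab <- if (use_unlabeled) benchmark$clinical_train$rois else NULL
  train_fpr(
    labeled, unlab,
    net_config = benchmark_net_config(config),
    loss_cfg = loss_config(),
    epochs = config$epochs, steps_per_epoch = config$steps_per_epoch,
    batch_labeled = config$batch_labeled,
    batch_unlabeled = config$batch_unlabeled,
    lr = config$lr, average_tail = 0.25,
    seed = seed, teacher = teacher,
    policies = arm_policies(augmentation)
  )
}

evaluate_fit <- function(fit, benchmark) {
  test <- benchmark$test
  scored <- test$rois
  scored$score <- predict(fit, scored$patch)
  det <- match_detections(scored, test$truths)
  froc_curve(det, n_scans = test$n_scans, n_truths = nrow(test$truths))
}

#' Run the four-arm ablation
#'
#' Trains and evaluates the 2 x 2 design (basic vs full augmentation,
#' without vs with unlabeled clinical data) on a shared synthetic benchmark
#' with shared seeds. The two supervised arms double as the phantom-trained
#' teachers for the matching semi-supervised arms. Training scan ids never
#' appear in the test set (asserted). Bootstrap confidence intervals are
#' reported for the two paired contrasts (full vs basic augmentation;
#' with vs without unlabeled data), computed on the first seed's
#' detections.
#'
#' @param config A [benchmark_config()].
#' @param seeds Integer vector of training seeds (the benchmark itself is
#'   built once from the first seed).
#' @param n_boot Bootstrap replicates for the contrast intervals.
#' @param benchmark Optionally a pre-built [build_benchmark()] result.
#' @return A list with `results` (tibble: arm, seed, cpm and the seven
#'   sensitivities), `contrasts` (tibble with bootstrap CIs) and the
#'   benchmark.
#' @export
run_ablation <- function(config = benchmark_config(), seeds = c(1L, 2L, 3L),
                         n_boot = 200, benchmark = NULL) {
  if (is.null(benchmark)) {
    benchmark <- build_benchmark(config, seed = seeds[1])
  }
  assert_no_leakage(benchmark)
  arms <- tidyr::expand_grid(
    augmentation = c("basic", "full"),
    use_unlabeled = c(FALSE, TRUE)
  )
  results <- list()
  det_store <- list()
  for (s in seeds) {
    teachers <- list()
    for (a in seq_len(nrow(arms))) {
      aug <- arms$augmentation[a]
      unl <- arms$use_unlabeled[a]
      arm_name <- paste0("unlab", ifelse(unl, "+", "-"),
                         "_aug", ifelse(aug == "full", "+", "-"))
      fit <- tryCatch(
        train_arm(benchmark, config, aug, unl, seed = s,
                  teacher = if (unl) teachers[[aug]] else NULL),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        results[[length(results) + 1L]] <- tibble::tibble(
          arm = arm_name, seed = s, cpm = NA_real_, failed = TRUE,
          message = conditionMessage(fit))
        next
      }
      if (!unl) teachers[[aug]] <- fit$net
      froc <- evaluate_fit(fit, benchmark)
      sens <- sensitivity_at(froc)
      row <- tibble::tibble(arm = arm_name, seed = s, cpm = cpm(froc),
                            failed = FALSE, message = NA_character_)
      names(sens) <- paste0("sens_fp", cpm_rates())
      results[[length(results) + 1L]] <-
        dplyr::bind_cols(row, tibble::as_tibble(as.list(sens)))
      if (s == seeds[1]) {
        scored <- benchmark$test$rois
        scored$score <- predict(fit, scored$patch)
        det_store[[arm_name]] <- match_detections(scored,
                                                  benchmark$test$truths)
      }
    }
  }
  contrasts <- list()
  if (all(c("unlab-_aug+", "unlab-_aug-") %in% names(det_store))) {
    ci <- bootstrap_cpm_diff(det_store[["unlab-_aug+"]],
                             det_store[["unlab-_aug-"]],
                             benchmark$test$truths, n_boot = n_boot,
                             seed = child_seed(seeds[1], 41L))
    contrasts[[1]] <- tibble::tibble(contrast = "aug+ vs aug- (unlab-)",
                                     diff = ci$diff, ci_lo = ci$ci[1],
                                     ci_hi = ci$ci[2])
  }
  if (all(c("unlab+_aug+", "unlab-_aug+") %in% names(det_store))) {
    ci <- bootstrap_cpm_diff(det_store[["unlab+_aug+"]],
                             det_store[["unlab-_aug+"]],
                             benchmark$test$truths, n_boot = n_boot,
                             seed = child_seed(seeds[1], 42L))
    contrasts[[2]] <- tibble::tibble(contrast = "unlab+ vs unlab- (aug+)",
                                     diff = ci$diff, ci_lo = ci$ci[1],
                                     ci_hi = ci$ci[2])
  }
  list(results = dplyr::bind_rows(results),
       contrasts = dplyr::bind_rows(contrasts),
       benchmark = benchmark)
}

assert_no_leakage <- function(benchmark) {
  train_ids <- c(benchmark$phantom$rois$seriesuid,
                 benchmark$clinical_train$rois$seriesuid)
  test_ids <- benchmark$test$rois$seriesuid
  if (length(intersect(train_ids, test_ids)) > 0) {
    stop("training/test scan id overlap detected", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the dataset-enlargement sweep
#'
#' Trains supervised models on nested subsets of labeled clinical scans,
#' with and without the phantom training set appended, and reports the
#' seven CPM-rate sensitivities per configuration on the shared test set.
#' The CPM column is recomputed from the sensitivity columns with [cpm()].
#'
#' @param config A [benchmark_config()].
#' @param tiers Increasing numbers of labeled clinical scans (nested
#'   subsets).
#' @param seed Training seed.
#' @param augmentation `"basic"` (the traditional trio) or `"full"`.
#' @param benchmark Optionally a pre-built [build_benchmark()] result.
#' @return A list with `table` (tibble: n_clinical, phantom, the seven
#'   sensitivity columns, cpm) and the benchmark.
#' @export
run_enlargement_sweep <- function(config = benchmark_config(),
                                  tiers = c(2, 5, 10), seed = 1L,
                                  augmentation = "basic",
                                  benchmark = NULL) {
  if (is.null(benchmark)) benchmark <- build_benchmark(config, seed = seed)
  assert_no_leakage(benchmark)
  stopifnot(!is.unsorted(tiers),
            max(tiers) <= benchmark$clinical_train$n_scans)
  clin <- benchmark$clinical_train$rois
  clin_ids <- unique(clin$seriesuid)
  rows <- list()
  for (tier in tiers) {
    subset_ids <- clin_ids[seq_len(tier)]   # nested by construction
    clin_sub <- clin[clin$seriesuid %in% subset_ids, , drop = FALSE]
    for (use_phantom in c(FALSE, TRUE)) {
      labeled <- if (use_phantom) {
        dplyr::bind_rows(clin_sub, benchmark$phantom$rois)
      } else clin_sub
      labeled <- oversample_positives(
        labeled, factor = balance_factor(labeled, config$oversample),
        seed = child_seed(seed, 61L + tier))
      fit <- train_arm(benchmark, config, augmentation,
                       use_unlabeled = FALSE, seed = seed,
                       labeled = labeled)
      froc <- evaluate_fit(fit, benchmark)
      sens <- sensitivity_at(froc)
      names(sens) <- paste0("sens_fp", cpm_rates())
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(n_clinical = tier, phantom = use_phantom),
        tibble::as_tibble(as.list(sens)),
        tibble::tibble(cpm = cpm(unname(sens)))
      )
    }
  }
  list(table = dplyr::bind_rows(rows), benchmark = benchmark)
}

#' Simulate a detection-set pair with a known sensitivity gap
#'
#' Constructs two synthetic scored detection sets over the same scan
#' population: system A detects each truth with probability `sens_a`,
#' system B with `sens_b`, detected truths score in `(0.5, 1)` and false
#' positives in `(0, 0.5)`. Because all detections outrank all false
#' positives, each system's sensitivity is flat across the CPM rates and
#' the true CPM difference equals `sens_a - sens_b`. Used to validate
#' bootstrap interval coverage.
#'
#' @param n_scans Number of scans.
#' @param truths_per_scan Truths per scan.
#' @param sens_a,sens_b Per-truth detection probabilities.
#' @param fp_per_scan False positives per scan (>= 8 so all CPM rates are
#'   achieved).
#' @param seed Integer seed.
#' @return A list with `det_a`, `det_b` (matched detection tibbles) and
#'   `truths`.
#' @export
simulate_detection_pair <- function(n_scans = 20, truths_per_scan = 3,
                                    sens_a = 0.8, sens_b = 0.6,
                                    fp_per_scan = 12, seed = 1L) {
  with_seed(seed, {
    truths <- tidyr::expand_grid(
      scan = seq_len(n_scans), t = seq_len(truths_per_scan))
    truths <- tibble::tibble(
      seriesuid = sprintf("s%03d", truths$scan),
      coordX = 100 * truths$t, coordY = 0, coordZ = 0,
      diameter_mm = 10
    )
    make_det <- function(sens) {
      hit <- stats::runif(nrow(truths)) < sens
      det_t <- tibble::tibble(
        seriesuid = truths$seriesuid[hit],
        coordX = truths$coordX[hit], coordY = 0, coordZ = 0,
        score = stats::runif(sum(hit), 0.5, 1)
      )
      fp <- tidyr::expand_grid(scan = seq_len(n_scans),
                               k = seq_len(fp_per_scan))
      det_f <- tibble::tibble(
        seriesuid = sprintf("s%03d", fp$scan),
        coordX = -50 * fp$k, coordY = 50, coordZ = 50,
        score = stats::runif(nrow(fp), 0, 0.5)
      )
      match_detections(dplyr::bind_rows(det_t, det_f), truths)
    }
    list(det_a = make_det(sens_a), det_b = make_det(sens_b), truths = truths)
  })
}
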
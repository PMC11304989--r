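# nodulefpr

Semi-supervised false-positive reduction for lung-nodule CADe, trained on
labeled anthropomorphic-phantom CT scans plus unlabeled clinical scans.

## The problem

The second stage of a lung-nodule CADe (computer-aided detection) system
classifies candidate regions of interest (ROIs) proposed by a
high-sensitivity first stage as nodule or non-nodule. Training that
classifier normally consumes thousands of expert-annotated clinical ROIs.
`nodulefpr` implements an alternative: use CT scans of a physical thorax
phantom — whose manufactured nodules come with perfect labels — as the
labeled training set, and fold real clinical scans in *without* labels
through consistency training and pseudo-labeling.

The training objective is

```
L = ls + lambda1 * lu + lambda2 * lp,      lambda1 = lambda2 = 0.5
```

where every term is a focal loss `FL(p, y) = -alpha (1 - pt)^gamma log(pt)`
(`alpha = 16`, `gamma = 2`, `pt = p` if `y = 1` else `1 - p`):

* `ls` — supervised loss on labeled ROIs (one augmentation operator drawn
  uniformly from {identity} ∪ menu per sample);
* `lu` — consistency loss between a weakly augmented view (flip, small
  translation) and a strongly augmented view (plus rotation / rescale /
  noise / intensity / blur / cutout) of each unlabeled ROI, active only
  when the weak view is confident (`max(p, 1 - p) >= 0.95`);
* `lp` — focal loss against pseudo-labels a phantom-trained teacher
  assigned before training (score ≤ 0.01 → negative, ≥ 0.99 → positive,
  otherwise abstain).

The classifier is a compact 3D CNN: three blocks of two 3 × 3 × 3
convolutions (32 / 64 / 128 kernels, leaky ReLU, 2 × 2 × 2 max pooling,
dropout 0.3), then global average pooling and two 128-node dense layers
(dropout 0.9) ending in one sigmoid logit. It is implemented in plain R on
top of BLAS (im2col + GEMM), with hand-derived backpropagation that the
test suite verifies against finite differences.

Detection performance is evaluated with free-response ROC (FROC) analysis:
a candidate is a true positive when its centre lies within half a diameter
of an annotated nodule; the CPM (competition performance metric) is the
mean sensitivity at 0.125, 0.25, 0.5, 1, 2, 4 and 8 false positives per
scan, with bootstrap confidence intervals for CPM differences obtained by
resampling scans.

Because phantom archives and clinical databases cannot ship with a
package, a simulator generates both: phantom-like thorax volumes whose
nodules come from a fixed 48-piece inventory (4 shape families ×
diameters 5–20 mm × densities −630 / −10 / 100 HU), and clinical-like
volumes with textured parenchyma, airways, vessel trees and scar-like hard
mimics. Volumes read and write as MetaImage (`.mhd/.raw`) or NIfTI, and
candidate/annotation tables use the LUNA16 CSV dialect
(`seriesuid, coordX, coordY, coordZ, class | diameter_mm`), so the same
pipeline runs on real data.

## A worked example

Simulate a phantom scan, preprocess it, and score its stage-1 candidates
with a freshly trained (tiny) classifier:

```r
library(nodulefpr)

# one phantom layout with nodules from the 48-piece inventory
layouts <- phantom_layouts(n_scans = 1, seed = 7)
scan    <- generate_phantom_scan(layouts[[1]])
scan$volume
#> <ct_volume> 40 x 64 x 64 voxels (z, y, x)
#>   spacing: 3 x 1.875 x 1.875 mm
#>   origin:  0, 0, 0 mm
#>   range:   [-1051.87, 112.082]
scan$annotations
#> # A tibble: 2 x 6
#>   seriesuid    coordX coordY coordZ diameter_mm agreement
#>   <chr>         <dbl>  <dbl>  <dbl>       <dbl>     <int>
#> 1 phantom_0001   94.9   47.0   78.2          20         4
#> 2 phantom_0001   33.5   51.7   73.7          20         4

# stage-1 emulation, preprocessing, ROI extraction
cands <- propose_candidates(scan$volume, scan$annotations,
                            n_per_scan = 40, sensitivity = 1, seed = 1)
vol   <- normalize_intensity(resample_volume(scan$volume, c(3, 1.875, 1.875)))
rois  <- extract_rois(vol, cands, roi_size_mm = 30)   # 10 x 16 x 16 patches

# train a small supervised model on these labeled patches
fit <- train_fpr(rois, net_config = network_config(conv_kernels = c(4, 8, 16),
                                                   input_shape = c(10, 16, 16),
                                                   conv_dropout = 0.1,
                                                   fc_dropout = 0.5),
                 epochs = 5, steps_per_epoch = 10, batch_labeled = 8,
                 lr = 3e-3, seed = 1)
glance(fit)
#> # A tibble: 1 x 7
#>   epochs    ls    lu    lp  loss gate_fraction n_parameters
#>    <int> <dbl> <dbl> <dbl> <dbl>         <dbl>        <int>
#> 1      5 0.917     0     0 0.917             0        32373

# score and evaluate
scored <- rois
scored$score <- predict(fit, scored)
det  <- match_detections(scored, scan$annotations)
froc <- froc_curve(det, n_scans = 1, n_truths = nrow(scan$annotations))
cpm(froc)
#> [1] 0.7142857
```

The `lu = lp = 0` columns show the supervised limit (no unlabeled
stream); a CPM of 0.714 here means the model ranks, averaged over the
seven FP rates, 71% of the true nodules above the false candidates of
this single training scan. `cpm()` also works directly on seven sensitivities, e.g.
from the bundled published benchmark table:

```r
tab <- enlargement_benchmark()
row <- tab[tab$setting == "basic_aug" & tab$n_clinical == 5 & tab$phantom == 0, ]
cpm(as.numeric(row[paste0("sens_fp", cpm_rates())]))
#> [1] 0.6531429
```

The experiment harness reproduces the study designs at desk scale:
`run_ablation()` trains the four arms (± full augmentation × ± unlabeled
clinical data) on a shared synthetic benchmark, and
`run_enlargement_sweep()` grows a labeled clinical training set with and
without the phantom scans appended. See `vignette("methods")` for the
models, the simulator's scope, and every numerical choice.

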
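---
title: "Semi-supervised false-positive reduction for lung-nodule CADe: models, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised false-positive reduction for lung-nodule CADe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nodulefpr)
```

## The problem

A lung-nodule CADe (computer-aided detection) system typically works in two
stages: a high-sensitivity region-proposal stage emits hundreds of candidate
locations per CT scan, and a false-positive (FP) reduction stage classifies
the 3D region of interest (ROI) around each candidate as nodule or
non-nodule. The FP-reduction classifier is where most of the labeled-data
cost concentrates, because it needs thousands of expert-annotated ROIs.

`nodulefpr` implements and evaluates a training strategy for this second
stage that substitutes most of the expensive labels with two cheaper
resources:

1. **labeled scans of an anthropomorphic thorax phantom** — a physical chest
   model with manufactured nodules of known position, size, shape and
   density, scanned on a clinical CT system; and
2. **unlabeled clinical scans**, incorporated with semi-supervised
   consistency training and teacher-assigned pseudo-labels.

Because neither the phantom scan archive nor a clinical database ships with
the package, a simulator generates both kinds of volumes with full ground
truth, at configurable grid sizes. Everything downstream — preprocessing,
augmentation, the classifier, the objective, FROC scoring — is the method
itself and runs identically on real volumes read from MetaImage or NIfTI
files.

## The objective

Training minimizes

$$L = l_s + \lambda_1 l_u + \lambda_2 l_p, \qquad
  \lambda_1 = \lambda_2 = 0.5,$$

with all three terms instances of the focal loss

$$\mathrm{FL}(p, y) = -\alpha (1 - p_t)^\gamma \log p_t, \qquad
  p_t = \begin{cases} p & y = 1 \\ 1 - p & y = 0, \end{cases}$$

with $\alpha = 16$ and $\gamma = 2$ (with $\alpha = 1, \gamma = 0$ this is
binary cross-entropy, which the test suite checks against an independent
oracle).

* $l_s$ — supervised term on the labeled stream. Each labeled ROI passes
  through one operator drawn uniformly from {identity} ∪ the augmentation
  menu (`labeled_augment()`).
* $l_u$ — consistency term on the unlabeled stream. Each unlabeled ROI is
  rendered in a *weak* view (random flips, integer translations of up to
  10% of the patch extent) and a *strong* view (a weak view followed by one
  heavier operator: in-plane rotation ≤ 30°, isotropic rescale ± 20%,
  Gaussian noise, intensity scale/shift ± 0.2, Gaussian blur, or cutout).
  When the weak-view prediction is confident — $\max(p, 1-p) \ge \tau_c =
  0.95$ for the single-logit head — the strong view is pulled toward the
  hard label $[p_\text{weak} \ge 0.5]$. The gate keeps early, noisy
  predictions from training the network on its own mistakes; the recorded
  `gate_fraction` rises as training progresses.
* $l_p$ — pseudo-label term. Before training, a teacher network fully
  trained on phantom data alone scores the unlabeled ROIs; scores ≤ 0.01
  become negative pseudo-labels, ≥ 0.99 positive ones, everything else
  abstains. Pseudo-labeled samples additionally contribute a supervised
  focal loss (computed on the weak view).

Weight decay (default 1e-4) applies to convolution kernels only. The logged
per-epoch `loss` equals `ls + 0.5 * lu + 0.5 * lp` as an exact arithmetic
identity, which the tests assert.

With no unlabeled data the trainer reduces exactly to supervised focal-loss
training ($l_u = l_p = 0$ identically), giving the "no unlabeled" arms of
the experiment harness for free.

## The classifier

`network_config()` describes the FP-reduction network: three convolutional
blocks of 32, 64 and 128 kernels (3×3×3, two convolutions per block, leaky
rectifier with slope 0.01), 2×2×2 max pooling after each block with floor
division for odd extents (so the default 15×48×48 patch pools 15→7→3→1),
dropout 0.3 inside the blocks, then global 3D average pooling and two fully
connected layers of 128 nodes with dropout 0.9, ending in one sigmoid
logit. Confidence for the binary head is $\max(p, 1-p)$.

The implementation is pure R: each convolution is an im2col gather followed
by one BLAS matrix product, with samples of a batch stacked so a layer
costs 27 gathers and one GEMM per batch regardless of batch size; chunking
bounds the im2col buffer. Backpropagation is hand-derived and verified
against central finite differences in the test suite (relative error
~1e-7). The optimizer is Adam; `lr_decay` (cosine) and `average_tail`
(tail-averaged a.k.a. Polyak weights) are optional stabilizers used by the
benchmark harness.

A deliberate RNG discipline makes experiments comparable: initialization,
batch composition, dropout masks and per-sample augmentations each draw
from their own seed stream derived from `(seed, step)`. Two training runs
with the same seed but different augmentation policies or data streams
therefore share *all* nuisance randomness (common random numbers), so arm
contrasts are not diluted by batch-lottery noise.

## The simulator

`generate_phantom_scan()` renders a simplified thorax: air (−1000 HU)
around an elliptic body with a +40 HU wall, two ellipsoidal lungs of
foam-like parenchyma (−850 HU), and a branching tubular vascular insert
(+50 HU). Nodules come from a 48-piece catalogue — 4 shape families ×
diameters {5, 8, 10, 20} mm × densities {−630, −10, 100} HU — and, like a
physical inventory, each catalogue item is a *fixed shape realization*
(`shape_seed`) that recurs across scans. This redundancy is a property of
real phantom data (the same manufactured nodules are rescanned in many
layouts) and matters for the study: it creates the memorization regime in
which augmentation and unlabeled data have something to fix. Nodules are
rendered with Gaussian edge smoothing as partial-volume blur; additive
Gaussian noise (protocol `noise_hu`, default 12 HU) stands in for the
dose/pitch/kernel variation of a real protocol. Dedicated rules construct
the two non-analytic families: lobulated nodules are unions of 3–6 spheres,
spiculated ones a 0.35 d core plus 8–16 tapering spikes; both stay inside a
1.5 d bounding box. These construction rules are the package's own (only
the family names and the diameter/density inventory are constrained);
a radius-spread statistic separates spherical from spiculated masks with
accuracy > 0.9, a sanity floor for learnability.

`generate_clinical_scan(seed, difficulty)` layers clinical complexity on
the same thorax: textured parenchyma, denser bifurcating vessel trees, dark
airway tubes with soft walls, scar-like bright blobs that are *not* in the
ground truth (hard mimics), pleural-attached nodules, wider nodule
densities including calcified ones up to +400 HU, and per-nodule random
shapes. `difficulty` in [0, 1] scales all of these; at 0 the distribution
collapses to phantom mode. The knob is not calibrated against any clinical
database — it exists to create a controllable domain gap.

`propose_candidates()` emulates the union of stage-1 detectors: each truth
is recalled with probability `sensitivity` (centre jitter ≤ a quarter
diameter), and the remaining budget lands preferentially on bright
structures (vessels, wall), where real detectors false-alarm. Labels follow
the same hit criterion as the scorer.

What the simulator does **not** model: real CT reconstruction physics
(kernels, beam hardening, streaks), real anatomy (lobes, fissures,
mediastinal organs), annotation disagreement beyond a synthetic `agreement`
column, and scanner-specific noise textures. Passing the benchmark
therefore demonstrates that the training machinery behaves as designed
under a controlled domain gap — not that a particular CPM will be attained
on clinical data.

## Preprocessing

The standard pipeline (`preprocess_config()`): resample every scan by
trilinear interpolation to (2, 0.625, 0.625) mm, clip intensities to
[−1000, 400] HU and rescale linearly to [−1, 1] (the endpoints map exactly
to ±1), extract 30 mm cubic ROIs — 15×48×48 voxels at the target spacing —
centred on the voxel nearest the candidate (floor of the continuous index
for even extents; out-of-volume regions pad with −1, air), sample 1000
nodule-free negatives per scan uniformly over the parenchyma with the
candidate's ROI box required not to intersect any truth's bounding sphere,
and oversample positive ROIs 250-fold. A "30 mm ROI" is read as a 30-mm
cube; a 30 mm³ ball would be ~4 mm across, smaller than most nodules
studied. `filter_scans()` applies the acquisition-quality filter (slice
thickness ≤ 2.5 mm, uniform z steps to 1e-3 mm, no gaps).

## Evaluation

`match_detections()` applies the hit criterion — candidate centre within
`diameter / 2` of a truth centre (the simulator's truths are spheres, so
the bounding sphere *is* the boundary); multiple candidates may hit one
truth but it counts as detected once; candidates whose only hits are on
excluded findings (diameter ≤ 3 mm or reader agreement < 3, see
`filter_test_truths()`) count as neither TP nor FP. `froc_curve()` sweeps
all score thresholds; sensitivity at the seven benchmark rates (0.125–8
FP/scan) uses linear interpolation on the FP axis with step-hold below the
lowest achieved rate (`interpolation = "step"` switches to a pure step
function). The CPM is the arithmetic mean of the seven sensitivities;
`cpm()` accepts either a curve or the seven numbers directly, which is how
the bundled published table (`enlargement_benchmark()`) is cross-checked —
including one known row whose printed summary (0.761) disagrees with the
mean of its own printed sensitivities (0.768); the suite flags rather than
resolves it. `bootstrap_cpm_diff()` resamples *scans* (CPM is defined per
scan population) with replacement, 1000 replicates by default, and reports
the 2.5/97.5 percentile interval of the CPM difference.

## The desk-scale benchmark

`benchmark_config()` pins the synthetic study the harness runs
(`run_ablation()`, `run_enlargement_sweep()`): 12 phantom + 12
clinical-training + 20 clinical-test scans on 40×64×64 grids at
(3, 1.875, 1.875) mm; 4–7 nodules per phantom scan (the emulated phantom
database averages ~7.5); 40 candidates/scan at stage-1 sensitivity 0.95;
ROIs extracted at the native (3, 1.875, 1.875) mm spacing, hence 10×16×16
patches; a slimmed network (4, 8, 16 kernels, conv dropout 0.1, dense
dropout 0.5); 225 Adam steps (15 epochs × 15) of batch 6 + 6 at lr 3e-3
with tail-averaged weights over the final 25% of steps; positive
oversampling balances the classes. The full-scale constants (15×48×48
patches, 32/64/128 kernels, dropout 0.3/0.9, 1000 negatives/scan, 250×
oversampling) remain the package defaults and are exercised end-to-end by
the test suite; the benchmark sizes exist so the four-arm ablation and the
enlargement sweep complete on one CPU core in minutes.

Two desk-scale deviations from the full-scale defaults deserve their
rationale. The dense-block dropout of 0.9 is regularization for a
128-kernel network trained for many epochs; on the slim benchmark network
it suppresses logit growth entirely, so scores never leave ~0.5 and the
0.95 confidence gate cannot open — the benchmark therefore uses 0.5.
Training length was chosen so the labeled set is traversed several times:
the augmentation-vs-none contrast is only meaningful once the unaugmented
arm can begin to memorize its (deliberately redundant) phantom positives.
At this scale the pseudo-label thresholds 0.01/0.99 are rarely reached by
the teacher, so the $l_p$ term is usually inactive in the benchmark — the
thresholds are kept faithful rather than loosened.

The harness asserts *orderings and identities*, not magnitudes: CPM values
from a 225-step run on simulated data are not comparable to published
full-scale results, and contrasts between arms remain trend-level — seed
noise at this scale is of the same order as the effects.

## Numerical choices and degenerate inputs

* Coordinate model: LPS world coordinates, identity direction cosines
  (files with rotated axes are rejected), 0-based voxel indices, (z, y, x)
  internal axis order with CSV columns in (x, y, z).
* MetaImage payloads are 32-bit little-endian floats; truncated payloads
  and missing header fields raise errors naming the problem.
* `focal_loss()` clamps probabilities to (1e-7, 1 − 1e-7); the trainer
  aborts on non-finite loss.
* `consistency_loss()` with an empty gate returns exactly 0, not NaN.
* Nodules smaller than one voxel along any axis are a degenerate-shape
  error; overlapping nodules are a layout error; negative sampling fails
  loudly after bounded retries when the admissible region is too small.
* Max pooling of odd extents floors (15→7→3→1), making the dense-block
  input size deterministic; pooling argmax ties resolve to the first
  window element.

## Known limitations

* The simulator's realism ceiling (above) bounds what the benchmark can
  say about clinical performance.
* The pure-R network is practical at benchmark scale and supports the
  full-scale architecture functionally, but full-scale *training* on
  hundreds of thousands of ROIs calls for an accelerator-backed
  implementation; the package's value there is the objective, the data
  machinery and the evaluator.
* In-plane-only rotation is the default (anisotropic z spacing makes 3D
  rotation interpolation lossy).
* The strong-operator menu is configuration, not a claim about any
  specific published menu; only flip/translate are canonical weak
  operators.
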
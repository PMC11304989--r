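Package: nodulefpr
Title: Semi-Supervised False-Positive Reduction for Lung Nodule CADe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating the false-positive-reduction
    stage of a lung-nodule computer-aided detection (CADe) system when labeled
    clinical data are scarce. Provides a simulator for anthropomorphic
    phantom-like and clinical-like chest CT volumes with ground-truth nodules
    of four shape families, a candidate-proposal emulator, the standard
    resample/clip/rescale preprocessing with 30 mm cubic region-of-interest
    extraction, parameterized weak/strong 3D patch augmentations, a compact
    3D convolutional classifier trained with a composite objective (focal loss
    on labeled data, confidence-gated consistency loss and teacher
    pseudo-labels on unlabeled data), and free-response ROC evaluation with
    the competition performance metric (CPM) and bootstrap confidence
    intervals. Volumes are read and written as MetaImage or NIfTI; candidate
    and annotation tables follow the LUNA16 CSV dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
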
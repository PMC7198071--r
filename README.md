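# idsnet

Binary classification of breast-tumour histopathology images (benign vs
malignant, BreakHis-style collections) with a densely connected
convolutional trunk whose intermediate depths are tapped, re-weighted by
squeeze-and-excitation (SE) channel attention, and aggregated into a single
classification head. The package is for researchers who want a fully
inspectable, dependency-light reference implementation of this multi-depth
attention architecture — every forward and backward pass is plain R over
BLAS, verified by finite-difference gradient checks and loop-based oracles —
together with the surrounding protocol: dataset manifests, stratified and
patient-disjoint splits, rotation/mirror augmentation, a staged-learning-rate
Adam loop, and patient-level evaluation.

## The model

A DenseNet-121 trunk (dense layer *l* computes
`x_l = H_l([x_0, …, x_{l-1}])` with the bottleneck composite
BN→ReLU→1×1 conv→BN→ReLU→3×3 conv, growth rate k = 32, transition
compression θ = 0.5) is tapped after each of the three transition layers and
after the last dense block. Each tap passes through an SE module

    z_c = mean_{i,j} u_c(i,j)             (squeeze)
    s   = sigmoid(W2 · relu(W1 z + b1) + b2)   (excite, bottleneck ratio r = 8)
    ũ_c = s_c · u_c                        (rescale)

and a classification branch (global average pooling + batch norm). The four
branch vectors — 128, 256, 512 and 1024 channels at 28×28, 14×14, 7×7, 7×7
for 224×224 inputs — are concatenated (1920 dimensions) into one fully
connected softmax head trained with binary cross-entropy.

Evaluation uses two statistics: the image recognition rate
`IRR = N_correct / N_images` and the patient recognition rate
`PRR = (1/N) Σ_p N_rec(p) / N_p`, the unweighted mean over patients of each
patient's fraction of correctly classified images, reported overall and per
magnification.

## Worked example

A complete run at desk scale — generate a synthetic BreakHis-like dataset,
split, train a reduced network, evaluate:

```r
library(idsnet)

spec <- synthetic_spec(n_patients_benign = 5, n_patients_malignant = 5,
                       images_per_patient_per_magnification = 2,
                       image_size = 64, seed = 11)
records <- generate_dataset(spec, "synthetic_demo")   # 80 PNGs + manifest

split <- split_dataset(records, c(0.5, 0.2, 0.3), seed = 3)
#> dataset split (image mode, seed 3): 40 train / 16 validation / 24 test

cfg <- model_config(growth_rate = 8, block_depths = c(2, 2, 2, 2),
                    input_size = 64)
model <- build_idsnet(cfg, seed = 3)
fit <- train_idsnet(model, split,
                    train_config(epochs = 5, batch_size = 16,
                                 input_size = 64, normalize = "unit", seed = 3))
#> epoch   1  lr 3.00e-03  train loss 0.0995  train acc 0.954  val acc 0.688
#> epoch   2  lr 3.00e-03  train loss 0.0023  train acc 1.000  val acc 1.000
#> ...
#> epoch   5  lr 3.00e-03  train loss 0.0006  train acc 1.000  val acc 1.000

preds <- predict_idsnet(fit$model, split$test, normalize = "unit")
evaluate_by_magnification(preds)
#> recognition rates over 24 images from 10 patients
#>   overall  PRR 1.0000  IRR 1.0000
#>     40x    PRR 1.0000  IRR 1.0000  (6 patients, 8 images)
#>    100x    PRR 1.0000  IRR 1.0000  (3 patients, 5 images)
#>    200x    PRR 1.0000  IRR 1.0000  (5 patients, 5 images)
#>    400x    PRR 1.0000  IRR 1.0000  (6 patients, 6 images)
```

The training lines show: the six-fold augmented pool (40 originals → 240
images/epoch) is fit almost immediately because the synthetic classes are
separable by design; validation accuracy selects the checkpoint; the test
report breaks both recognition rates down by magnification. The same
separable dataset evaluated with a patient-disjoint split, or an
`overlap = 1` dataset (identical class textures), are the two controls the
test suite runs.

Inspecting the full-size default architecture:

```r
cmd_inspect_model()
#> architecture: k=32, depths [6,12,24,16], compression 0.50, r=8
#> taps (channels @ spatial): 128@28x28, 256@14x14, 512@7x7, 1024@7x7
#> concatenated feature dimension: 1920
#> parameters:
#>   trunk         6,962,048
#>   se              350,320
#>   branches          3,840
#>   final_fc          3,842
#>   total         7,320,050
```

## Command line

A thin dispatcher over the same functions lives at
`system.file("cli", "idsnet.R", package = "idsnet")`:

```sh
Rscript idsnet.R generate-synthetic --out data --image-size 64 --seed 11
Rscript idsnet.R split --manifest data/manifest.csv --out splits --mode patient
Rscript idsnet.R train --data data/manifest.csv --out run --config cfg.yaml
Rscript idsnet.R evaluate --out eval --checkpoint run/checkpoint.rds --manifest splits/test.csv
Rscript idsnet.R inspect-model --json
```

Real BreakHis image trees are read directly (`--data <dir>` or
`scan_breakhis_dir()`); the collection is optional and nothing in the
package requires downloading it.

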
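---
title: "Methods: a multi-depth DenseNet with squeeze-and-excitation taps for histopathology classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-depth DenseNet with squeeze-and-excitation taps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Benign/malignant classification of H&E-stained breast-tumour biopsy images,
acquired per patient at four optical magnifications (40x, 100x, 200x, 400x)
in the BreakHis layout.  Two properties of this data shape the design:
images come in patient groups, so both an image-level accuracy (IRR) and a
patient-level accuracy (PRR) matter; and discriminative texture lives at
several spatial scales, which motivates aggregating features from several
network depths rather than only the deepest layer.

## The model

The trunk is a densely connected convolutional network.  Layer $l$ of a
dense block computes

$$x_l = H_l([x_0, x_1, \dots, x_{l-1}]),$$

where $[\cdot]$ is channel concatenation and $H_l$ is the bottleneck
composite BN → ReLU → 1×1 conv (to $4k$ channels) → BN → ReLU → 3×3 conv
(padded, to $k$ channels); $k$ is the growth rate.  A block of $L$ layers
maps $C$ input channels to $C + Lk$.  Between blocks a transition layer
(BN → ReLU → 1×1 conv → 2×2 average pooling, stride 2) compresses channels
by $\theta = 0.5$ and halves the spatial size.  The stem is a 7×7 stride-2
convolution followed by BN, ReLU and 3×3 stride-2 max pooling.  With the
default $k = 32$ and depths 6/12/24/16 this is the standard DenseNet-121
trunk; its own global pooling and classifier are removed.

Four taps are taken from the trunk: the outputs of the three transition
layers and of the last dense block (128, 256, 512 and 1024 channels at
28×28, 14×14, 7×7 and 7×7 for 224×224 inputs).  Each tap feeds a
squeeze-and-excitation (SE) module:

$$z_c = \frac{1}{HW}\sum_{i,j} u_c(i,j), \qquad
  s = \sigma\!\big(W_2\,\delta(W_1 z + b_1) + b_2\big), \qquad
  \tilde u_c = s_c\, u_c,$$

with $\delta$ the ReLU, $\sigma$ the sigmoid, and $W_1 \in
\mathbb{R}^{C/r \times C}$, $W_2 \in \mathbb{R}^{C \times C/r}$ a bottleneck
of reduction ratio $r = 8$.  The re-weighted map enters a classification
branch — global average pooling followed by a branch-private batch
normalization — yielding one feature vector per depth.  The four vectors are
concatenated (1920 dimensions by default) and a single fully connected layer
with softmax produces the class probabilities.  Training minimizes the
binary cross-entropy $-(y\log p + (1-y)\log(1-p))$, averaged over the batch.

## Design choices where the design was open

* **Bottleneck composite.** The plain BN–ReLU–3×3 composite cannot account
  for a 121-layer network at depths 6/12/24/16; only the bottleneck variant
  (two convolutions per dense layer) does.  The bottleneck width factor is
  configurable.
* **Growth rate.** The default is $k = 32$: an ImageNet-pretrainable
  DenseNet-121 trunk with a ~7M-parameter budget requires it.  $k = 12$ is a
  supported configuration (`model_config(growth_rate = 12)`), but note taps
  must stay divisible by $r$.
* **SE placement.** `"branch"` (default) applies SE off-path: the trunk is
  untouched and only the classification branch sees the re-weighted map.
  `"in_path"` also routes the SE output into the next trunk stage.  Both are
  implemented and gradient-checked; the default follows the reading in which
  transition outputs are fed "into their SE module followed by the
  classification sub-network".
* **Branch output.** Branches emit the GAP+BN feature vector; softmax is
  realized once, after concatenation, at the final head.  Concatenating
  per-branch probabilities instead would make a 1920-wide final layer
  meaningless.  An optional deep-supervision mode
  (`deep_supervision = TRUE`) adds per-branch two-way softmax heads whose
  losses are averaged into the objective; it is off by default.
* **Stem order.** The stem uses the standard Conv → BN → ReLU order (the
  alternative BN-first stem is incompatible with pretrained trunk weights).
* **Other conventions.** SE bottleneck layers carry biases (switchable);
  $C$ divisible by $r$ is enforced at construction rather than rounding
  $C/r$; transition pooling floors odd spatial sizes; every branch BN keeps
  its own running statistics and inference uses them; probabilities are
  clamped to $[10^{-7}, 1-10^{-7}]$ inside the loss, which is otherwise
  undefined at $p \in \{0, 1\}$.

## Training protocol

Adam with $\beta_1 = 0.9$ (the protocol's "momentum"; Adam has no classical
momentum term), $\beta_2 = 0.999$, 60 epochs, batch size 64.  The learning
rate is piecewise constant: 3e-3 for epochs 1–24, halved at epoch 25 and
again at epoch 30 (the only reading of "lowered by a factor of 2 at epochs
25 to 30" that connects smoothly to the later values), 3e-5 from epoch 35
and 1e-5 from epoch 40 onward.  The training pool is expanded six-fold: the
original plus rotations by 90/180/270 degrees and horizontal and vertical
mirrors — "five times more data" read as five new variants per original,
the only reading consistent with the five listed transforms.  The model
with the highest validation accuracy is kept, earliest epoch on ties.
Repeats re-randomize both the split and the initialization from consecutive
seeds.  A `transformation_rate = 0.05` constant appears in the protocol
with no defined semantics; it is stored in `train_config()` and unused.

Splitting defaults to image-level 50/20/30, stratified by class, mirroring
a protocol that pools patients and magnifications before dividing.  This
leaks patient identity between train and test; `mode = "patient"` assigns
whole patients to subsets and is the recommended setting for honest
generalization estimates.  The stated protocol sizes (3954 training, 2370
validation images of 7909) are mutually inconsistent with 50/20/30; the
fractions take precedence.

## The synthetic dataset

`generate_dataset()` emulates the BreakHis layout — PNG tree, file-name
dialect, patient grouping, per-magnification counts — with class-dependent
texture caricatures: sparse, round, regular "nuclei" on a pink background
for the benign class; dense, irregular, high-frequency blobs on a purple
background for the malignant class.  Magnification scales blob size (and
thins blob counts), and every synthetic patient receives a small
patient-specific hue jitter so that image-level and patient-disjoint splits
measurably differ.  An `overlap` knob pulls both classes toward their common
midpoint; at `overlap = 1` the class distributions coincide.

What the generator does *not* emulate: stain physics, tissue morphology,
scanner artifacts, label noise, or the class imbalance of real collections.
Tests passing on synthetic data certify the machinery — shapes, gradients,
determinism, protocol, metrics — and that the network can learn a cleanly
separable signal; they say nothing about accuracy on real histology.

Two properties are asserted by tests: at default parameters a logistic
classifier on mean-channel features separates the classes (learnability
floor), and at `overlap = 1` a trained network stays at chance.  The
negative control is evaluated under a **patient-disjoint** split: because
the hue jitter identifies patients, an image-level split lets a network
genuinely recognize test images of memorized patients and score well above
chance even with identical class textures — the leakage the patient-disjoint
mode exists to prevent.

## Numerical implementation

Tensors are `(H, W, C, B)` double arrays.  Convolutions are evaluated as a
single BLAS matrix product over an im2col patch matrix whose index map is
cached per shape; backward passes are hand-derived and verified against
central finite differences at probe points through the assembled network
(tolerances 1e-5 to 1e-3 relative).  Batch normalization uses the biased
variance for normalization, the unbiased one for running statistics
(momentum 0.1, eps 1e-5), and running statistics in inference.  Fresh
weights are He-uniform; builds are seeded.  Forward passes in inference
mode are deterministic; training is deterministic given the seed up to
BLAS summation order.

Desk-scale problem sizes used by the tests and the acceptance script, all
package choices: 64×64 synthetic images, 10 patients, growth rate 8 with
block depths 2/2/2/2 (~30k parameters), at most 10 epochs at batch 16, with
plain unit normalization since synthetic intensities are already in [0, 1].
Under these conditions the separable dataset is learned to perfect training
accuracy within a few epochs, and the overlap-1 control stays at chance.

## Known limitations

Single-threaded CPU implementation intended for desk-scale verification and
small studies, not for training the full 224×224 network on 8k images;
binary heads by default (K is configurable but untested beyond small K); no
stain normalization or patch extraction; pretrained ImageNet weights are
supported only as a trunk-shaped checkpoint produced by this package
(`load_pretrained_trunk()`), since no converter from external formats is
included.
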
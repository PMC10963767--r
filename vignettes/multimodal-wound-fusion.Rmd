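---
title: "Multi-modal wound classification: model, pipeline and design notes"
author: "woundfusion"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Multi-modal wound classification: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Chronic wounds — diabetic, pressure, surgical and venous ulcers — are
routinely photographed in wound care, and the anatomical site of a wound is
strongly informative about its aetiology: diabetic ulcers concentrate on the
foot, venous ulcers on the lower leg and malleolus, pressure ulcers over
bony prominences. `woundfusion` implements a classifier that fuses both
signals: the wound image (a rectangular region of interest, resized to a
square input) and the wound's anatomical location on a numbered body map of
484 regions, encoded one-hot.

The architecture has three parallel convolutional branches — truncated
ResNet152, VGG16 and EfficientNet-B2 feature extractors at full scale, or
three small conv stacks (`tiny_a/b/c`) at desk scale. Their feature maps are
aligned by adaptive average pooling to the smallest branch grid and
concatenated along channels. The fused map passes through repeated blocks of

* **ConvBlock** — a same-padded convolution followed by ReLU;
* **P_scSE** — channel squeeze-and-excitation (`s = sigmoid(W2 relu(W1 z))`,
  `z` the channel means, output `s_c * x_c`) and spatial
  squeeze-and-excitation (`q = sigmoid(conv1x1(x))`, output `q_hw * x_chw`)
  run in parallel and merged as `max(a, b) + (a + b)`;
* dropout.

The result is flattened, passed through a dense layer, and then a head of
two dense layers each followed by **axial attention** — scaled dot-product
self-attention restricted to one axis of a feature grid at a time — ReLU and
dropout. When the location branch is enabled, the 484-length one-hot
location runs through an **adaptive-gated MLP**: a ReLU expansion split into
a value half and a gate half, axial attention over the gate half, a sigmoid
gate multiplying the value half, and an output projection. Its output is
concatenated with the head features before the final dense layer, which maps
to the K class logits. Training minimises multi-class cross-entropy
`L = -sum_i y_i log(p_i)` with Adam.

## What is implemented where

Everything numerical is implemented in base R over BLAS: convolution
(shift-and-matmul), pooling, batch normalisation, dense layers, attention,
the custom blocks, and exact hand-derived backward passes for all of them
(verified against finite differences in the test suite, relative tolerance
1e-3 on tiny instances). EBImage stands behind image I/O and the geometric
augmentations; pROC behind the ROC curves; everything else in the pipeline
is package code.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lr` / `lrMin` | 1e-4 / 1e-5 | Adam learning rate and schedule floor (reference recipe) |
| `batchSize`, `epochs` | 32, 100 | reference training settings |
| `schedFactor`, `schedPatience` | 0.5, 5 | reduce-on-plateau decay and patience (epochs) |
| `dropout` | 0.3 | dropout rate in aggregation and head |
| `seReduction` | 16 | squeeze-and-excitation bottleneck ratio `r` (ceiling rounding) |
| `fusionChannels` | 24 (tiny) / 64 (canonical) | channels of the aggregation ConvBlocks |
| `aggregationRepeats` | 2 | ConvBlock + P_scSE + dropout repeats |
| `headWidths` | (64, 64) | dense head widths; 64 reshapes to an 8x8 attention grid |
| `gmlpHidden`, `gmlpOut` | 128, 32 | location branch expansion and output width |
| `locationAssoc` | 0.9 | synthetic class-location association probability |
| augmentation probabilities | 0.5 each | rotation (±30°), flips, affine (scale 0.9–1.1, shift ≤10%, rotate ±15°), Gaussian noise (σ = 0.03), coarse dropout (≤8 holes of 8–32 px) |

The augmentation magnitudes are conventional ranges — the method's identity
does not depend on them — and every one is overridable in `augmentConfig()`.
Normalisation defaults to the ImageNet channel statistics that pretrained
backbones expect.

## Design choices where the design was genuinely open

* **Split allocation rule.** Published per-class split counts are
  reproduced exactly by `train = floor(f_train n)`, `val = floor(f_val n)`,
  `test = remainder` per class (the validation column equals
  `floor(0.15 n)` in every row, which rules out val-gets-remainder). The
  floor is computed with a 1e-9 guard because binary floating point makes
  `0.7 * 100` slightly less than 70. Assignment within a class is a
  seed-deterministic shuffle. Group-aware splitting (all images of one
  wound in one subset) is available as a flag; it packs whole groups
  greedily into the subset with the largest remaining deficit and reports
  achieved counts, since exact floor counts and group atomicity can
  conflict. A class with fewer records than nonzero subsets triggers a
  warning (not an error): the arithmetic still produces a valid partition,
  with the remainder in the test subset.
* **P_scSE merge.** "Max-out and addition" is read literally as
  `max(a, b) + (a + b)`; `max`-only and `add`-only merges are available
  behind `mergeMode` so the reading is falsifiable.
* **Axial attention on flat vectors.** Dense-layer features have no spatial
  axes, so an F-vector is reshaped to the smallest square grid
  (zero-padded), attended along rows then columns (single head), and
  flattened back. This gives the one-axis-at-a-time semantics a concrete,
  testable form; with one trivial axis it provably reduces to full
  self-attention. Residual connections around attention and layer
  normalisation in front of each attention are included (the standard
  companions of residual attention; without normalisation the attention
  inputs grow in scale during training and the loss oscillates).
* **Adaptive-gated MLP wiring.** One ReLU expansion, an even split into
  value and gate halves, axial attention on the gate half, sigmoid gate,
  output projection. The exact number of stages is a documented choice, not
  a claim about any reference implementation; the gating contract (closed
  gate blocks all location signal) is what the tests pin down.
* **Backbone truncation recipes.** Layer counts are ambiguous without a
  granularity convention, so each cut is a named, versioned recipe:
  `vgg16-drop12-v1` counts 13 conv + 5 pool + 3 FC layers and drops the
  last 12, keeping conv1_1..conv3_3 (256 channels at 1/4 resolution);
  `resnet152-midcut-v1` removes pooling/FC, ends inside the third
  bottleneck of stage 2 with that block's last two modules (the expanding
  1x1 convolution and its batch norm) removed, and drops later stages (128
  channels at 1/8); `efficientnet_b2-dropclassifier-v1` removes only the
  classifier (1408 channels at 1/32). The fusion design does not hinge on
  the exact cut; the recipes make it reproducible.
* **Spatial alignment.** Branch grids differ (64/32/8 at 256 px input);
  all are adaptive-average-pooled to the smallest grid before channel
  concatenation — minimal information loss and shape-safe for any input
  size.
* **Model selection.** When a validation set exists, the checkpoint with
  the best validation accuracy is retained and evaluated; without one
  (e.g. cross-validation folds) the final epoch is used and the plateau
  schedule monitors the training loss. The selection rule is ours and
  documented, since test-time selection is otherwise unspecified.
* **Metric averaging.** Precision/recall/F1 are support-weighted —
  weighted recall then equals accuracy algebraically, the signature visible
  in the reference tables where the recall column always equals the
  accuracy column. Macro averages are also reported.
* **Initialisation and optimisation safeguards.** He-uniform for
  convolutions and dense layers, a small positive bias (0.01) in the
  squeeze-and-excitation bottleneck so the ReLU is not dead at
  initialisation, a zero-initialised output layer so the initial loss is
  exactly `log K`, and global gradient-norm clipping (`gradClip`, default
  1, 0 disables) in the trainer. When a validation set is present,
  checkpoint-selection ties on validation accuracy are broken by the lower
  validation loss, so a barely-trained early epoch never wins a tie
  against a converged one.

## The synthetic generator and what passing tests do and do not show

`generateSynthetic()` emulates the statistical structure the method
assumes, not wound photography: class-conditional appearance separable by
colour and texture (background = smooth dark gradient; normal skin = noisy
skin tone; wound classes = elliptical lesions with class-specific hue,
granularity, eccentricity and edge darkness) and a configurable association
between class and body-map location (`locationAssoc`: preferred-set draw
versus uniform over 1..484). Preferred sets are small (8 region IDs per
wound class, pairwise disjoint, clinically plausible — foot for diabetic,
malleolus for venous) so that locations recur between training and test:
a one-hot encoding cannot generalise to region IDs never seen in training,
which is equally true of the real model. The `ambiguousPair` option renders
two classes with a single shared appearance, making location the only
separating signal — the desk-scale analogue of the image+location gain.

Desk-scale study conditions, chosen once: 32x32 images, tiny backbones,
Adam at 1e-3 (the standard Adam default; the 1e-4 reference rate belongs to
fine-tuning pretrained backbones at full scale), batch 8. The overfitting
experiment uses 4 classes x 8 images for 50 epochs with dropout and
augmentation off — an overfitting check measures capacity, not
regularisation. The multi-modal advantage experiment uses an ambiguous D/V
pair, 30 images per class, `locationAssoc = 0.95`, a 60/15/25 split and 25
epochs, compared with and without the location branch over 5 seeds; it
trains with the regular pipeline — augmentation on (coarse-dropout holes
scaled to 4-8 px for 32 px images) and dropout 0.3 — because with no
regularisation the tiny network simply memorises the 36 training images
and nothing forces any signal through the location branch (shortcut
learning); the regularised pipeline is also what the method prescribes for
training.

Passing these tests shows the architecture is trainable end-to-end, that
its gradients are exact, and that the location branch carries class signal
through the gate when images do not. It does not show anything about
photographic wound images, pretrained-feature quality, or clinical
performance — reproducing the reference accuracies requires the original
datasets and GPU-scale transfer learning, which is out of scope here.

## Numerical notes and degenerate inputs

* Probabilities inside the cross-entropy are clamped at 1e-12; a non-finite
  training loss aborts with a diagnostic rather than continuing.
* Softmax and attention weights subtract the row maximum before
  exponentiation.
* `max(a, b)` ties in the P_scSE merge route their gradient to the cSE
  branch (the `a >= b` convention).
* A class with a single record splits as (0, 0, 1) — floors are zero, the
  remainder goes to test.
* One-hot positions are ranks in ascending ID order, so sparse or
  non-contiguous custom vocabularies work; encoding an unregistered ID is
  an error, not a silent zero vector.
* Batch normalisation uses batch statistics during training and running
  statistics (momentum 0.1) at evaluation.

## Known limitations

* Pure-R training is CPU-bound: the full-scale three-backbone network
  builds and runs forward, but training it at 256x256 is not practical in
  this implementation; the tiny backbones are the supported training path.
* Pretrained weights are not bundled; `pretrained = TRUE` requires a
  user-supplied parameter file.
* Grad-CAM taps the top-level convolutions of each branch (every branch
  ends in one by construction of the recipes).
* The body-map region *names* beyond the handful of published examples are
  placeholders; all logic depends only on IDs.
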
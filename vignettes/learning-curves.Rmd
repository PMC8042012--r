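---
title: "Methods: learning-curve analysis for leukocyte image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning-curve analysis for leukocyte image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Annotated single-cell images from blood smears are expensive: an expert
cytologist has to label every cell. Before committing to a large annotation
campaign it is worth knowing how classifier performance actually scales with
training-set size. `cytocurve` implements the complete apparatus for that
question — a small convolutional classifier, a nested incremental
cross-validation protocol, and introspection tools — together with a
synthetic image generator so that the whole pipeline is testable without any
external image collection.

## The synthetic cell generator

Real blood-smear datasets of this kind (a few hundred single-cell crops of
leukocytes from leukemia patients and controls) cannot be redistributed, so
the package ships a generator instead of images. Each sample is a centered
elliptical cell on a stained background: the nucleus is drawn as
`lobe_count` overlapping or ring-separated circular lobes occupying a target
fraction of the cell area (the nucleus:cytoplasm ratio), with Gaussian
"chromatin" brightness noise inside the nucleus, per-image color jitter,
optional red-cell-like background discs, and global sensor noise. Class
specifications follow standard cytology descriptions: blasts have a large
round nucleus with high N:C ratio (mean 0.75) and fine chromatin; typical
lymphocytes a compact nucleus (N:C mean 0.45); segmented neutrophils 2–5
lobes; monocytes a large indented (two overlapping lobes) nucleus;
thrombocytes are small anucleate fragments. Every parameter is a
distribution, and every one is overridable.

Two knobs matter for testing:

* `effect_size` interpolates all class parameters between the pooled mean
  (0: classes identical by construction) and their full class-specific
  values (1). A threshold classifier on the measured N:C ratio has AUC ≈ 0.5
  at 0 and AUC ≈ 1 at 1, monotonically in between.
* `distractors` places erythrocyte-like discs in the background (default
  on), so a classifier must localize the leukocyte; this is what makes the
  saliency/relevance analyses informative rather than trivial.

The generator also returns its own ground-truth nucleus and cell masks,
which `measure_morphology()` uses for validation (area fraction, connected
lobe components via `EBImage::bwlabel`, mean color). What the generator does
*not* emulate: real staining variability, focus artifacts, touching cells,
patient identity (the modeled datasets provide none), or the four rare
diagnostic classes with fewer than five images. Passing tests on synthetic
data therefore validate the *pipeline* — protocol correctness, optimization,
metric arithmetic, attribution faithfulness — not clinical performance on
real smears.

## The network

The classifier is a deliberately small sequential CNN: six pairs of 3×3
valid-padding convolutions (filters 4, 8, 8, 8, 16, 16, rectifier
activations) each followed by 2×2/stride-2 max pooling, a flatten, a 32-unit
rectifier dense layer (the penultimate representation), and a softmax
output. For a 257×257 RGB input this gives exactly 7210 parameters with a
2-way output and 7342 with a 6-way output; for 400×400 it gives 13354.

The padding/pooling/width configuration is *derived*, not assumed: with
3-channel input the first convolution contributes 3·3·3·4+4 = 112
parameters (a grayscale input would give 40), and only valid padding with
floor-halving pooling traces 257 → 255, 127, 125, 62, 60, 30, 28, 14, 12,
6, 4, 2, flattening to 2·2·16 = 64 and hence 64·32+32 = 2080 hidden-dense
parameters; `same` padding would flatten to 256 and give 13354 total. The
two published totals jointly pin down every choice, and
`count_parameters()`/`spatial_trace()` make the accounting explicit.

Six valid-conv/pool stages need roughly 190 px of input; smaller images use
the same architecture with fewer pairs (`max_conv_pairs()`), keeping the
32-unit penultimate layer. The 65 px setting used in the scaled experiments
runs four pairs (2698 parameters). Weights initialize from a uniform
fan-in-scaled distribution (`U(±sqrt(6/fan_in))`), biases at zero, under a
recorded seed.

## The protocol

Tenfold cross-validation with a twist that makes learning curves cheap and
paired: in each fold, 10% of the images are a test set (every image is
tested in exactly one fold); of the remainder, 25 images form a fixed
validation set and the rest a training pool. The pool is shuffled once and
the nested training subsets are its growing prefixes (10, 20, …, 200 by
default), so each subset contains the previous one and, within a fold, all
sizes share the same test and validation sets. Splits are unstratified
uniform-random; a balanced-test variant (for large collections: e.g. a
600-image balanced test set per fold, disjoint across folds on the test
side only) is available via `balanced_test = TRUE`.

Training minimizes cross-entropy with Adam. The source protocol leaves the
optimizer, learning rate, batch size and epoch cap unstated; the defaults
here (learning rate 1e-3, batch 16, `max_epochs` 500) are ordinary
small-CNN settings, exposed in `protocol_config()`. Early stopping halts
training once the validation loss has not decreased for 50 epochs
(`early_stop_patience`) and restores the weights of the best epoch, earliest
epoch winning ties.

Augmentation applies, independently per image: horizontal and vertical
flips with probability 0.5 each, and rotation by an angle uniform on
[0°, 359°] (bilinear, constant fill equal to the configured background
color or the image's border median; values clipped to [0, 1]). The phrase
"adding a random number of augmented images each epoch" admits two
readings, and both are implemented: the default re-augments every training
image once per epoch (`augment_mode = "replace"`), the literal reading
appends `k ~ U{0..n}` augmented copies to the untouched originals
(`"append"`). Multiclass training first balances the training set to a
fixed per-class size (default 150) by keeping all originals and topping up
with augmented copies — or subsampling classes above target — with ancestor
ids recorded.

Seeding is hierarchical: a master seed plus fold/size indices are mixed
through a multiplicative hash (`derive_seed()`), so any single training run
can be reproduced in isolation and the whole learning-curve table is
bit-reproducible.

## Evaluation conventions

* **ROC-AUC** is computed by the rank (Mann-Whitney) formula, ties counting
  one half; it equals the trapezoidal area under the empirical curve, and
  the test suite holds it to a brute-force pairwise oracle at 1e-12.
* **Fold-averaged ROC** uses vertical averaging: linear interpolation of
  each fold's TPR on a 101-point FPR grid. Both the AUC of the mean curve
  and the mean ± sd of per-fold AUCs are reported, since they differ in
  general.
* **F1** is macro-averaged (the motivation for using F1 at all is test-set
  imbalance, which micro-averaging would re-introduce); per-class F1 is 0
  when precision + recall is 0. Micro/weighted variants are a trivial
  extension but not exposed.
* **Confusion matrices** report row percentages with the per-class n
  alongside; a class absent from the truth yields an `NA` row, never 0/0.
* **Box summaries** use type-7 (linear-interpolation) quartiles; whiskers
  reach the most extreme points within 1.5 IQR of the box, everything
  beyond is listed as an outlier. The convention only matters at small n
  (10 folds), which is exactly where it is used, hence it is pinned by
  tests.

## Interpretability

* **Saliency**: absolute gradient of the target class's *pre-softmax logit*
  with respect to each input pixel, reduced over RGB by the maximum
  (sum-abs available). The logit, not the probability, is explained —
  standard for both methods, and it keeps saliency and LRP comparable.
  Faithfulness is tested against central finite differences (1e-4
  relative).
* **LRP** uses the stabilized epsilon rule (ε = 1e-6) for dense and
  convolution layers — implemented as `R_in = x ⊙ Wᵀ(R / (z + ε·sign z))`,
  reusing the convolution backward kernel — winner-takes-all routing
  through max-pooling (the recorded argmax), and channel-summing at the
  input. With zero biases the map total equals the explained logit up to
  epsilon leakage (tested at 1%); nonzero biases absorb relevance, which is
  inherent to the rule, not a defect. An α=1/β=0 positive-contributions
  rule is available via `rule = "alpha_beta"`.
* **Embedding**: exact O(n²) t-SNE (perplexity calibration by bisection,
  early exaggeration ×12 for 100 iterations, momentum 0.5→0.8, adaptive
  gains, seeded initialization) — adequate for the few hundred samples
  embedded here. Class separation is quantified as the mean silhouette
  width (`cluster::silhouette`), either on the 2-D embedding or directly on
  the 32-D penultimate activations; the learning-size comparison uses the
  32-D score to avoid confounding by the embedding.

## Problem sizes used in tests and the analysis scripts

The shipped experiments run a structurally identical, scaled version of the
full protocol: 65×65 px images, 250 images (125 per class), full effect
size, 5 folds, nested sizes {10, 30, 60, 100}, `max_epochs` 80 and patience
20. These sizes were fixed as the package's standard desktop-scale study.
On fully separable synthetic morphology the network reaches near-ceiling
test AUC from ten training images on, so the saturation property (the mean
AUC at 30 images within 0.05 of the large-sample mean) holds with a wide
margin, while the internal representation keeps sharpening: the silhouette
separation of the penultimate activations is higher for the 100-image
models than for the 10-image models in at least four of the five folds.
The test suite computes exactly these three quantities. The full-scale
constants (257 px, 10 folds, sizes 10–200, patience 50, epoch cap 500)
remain the package defaults.

## Degenerate inputs and numerical details

* Softmax is computed with max-subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Max-pooling ties go to the earliest element in column-major order — the
  same index backprop and LRP routing use, keeping all three consistent.
* An all-identical activation matrix is rejected by t-SNE with a warning
  and a zero embedding (flagged), rather than NaNs.
* `roc_auc` and `separation_score` refuse single-class inputs explicitly.
* Image sizes below 32 px are rejected by the generator as configuration
  errors; network construction errors name the first layer whose spatial
  size would underflow.

## Known limitations

* The generator's morphology is a caricature: sufficient to order classes
  by separability and to exercise localization, not to transfer conclusions
  about absolute accuracy to stained smears.
* Training is single-threaded on CPU; the full 257-px, 10-fold, 20-size
  protocol is an overnight job, which is why the scaled setting exists.
* The real datasets' headline scores (binary ROC-AUC ≈ 0.97, macro
  F1 ≈ 0.81) depend on images this package deliberately does not ship;
  nothing here claims to reproduce those numbers, only the protocol that
  produced them.
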
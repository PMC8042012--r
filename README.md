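# cytocurve

How many annotated single-cell images does a convolutional classifier of
leukocyte morphology actually need? `cytocurve` implements the full
apparatus for answering that question as a learning-curve experiment: a
small sequential CNN with exact parameter accounting, a nested incremental
cross-validation protocol, flip/rotation augmentation and per-class
balancing, ROC/F1 evaluation, and model introspection (gradient saliency,
layer-wise relevance propagation, t-SNE of the penultimate layer). Because
the blood-smear image collections this protocol targets cannot be
redistributed, the package ships a seeded synthetic single-cell image
generator with controllable class-conditional morphology, so every stage is
testable and every experiment reproducible from a single seed.

It is aimed at researchers in computational hematology / biomedical image
analysis who want to plan annotation budgets or audit sample-size claims.

## The model and protocol

The classifier is a sequential CNN of six (convolution 3×3, valid padding,
rectifier) + (max-pool 2×2, stride 2) pairs with filter counts
4, 8, 8, 8, 16, 16, then flatten → dense(32, rectifier) → dense(C, softmax).
Parameter accounting follows k²·c_in·c_out + c_out per convolution and
n_in·n_out + n_out per dense layer: for 257×257 RGB input this yields
exactly **7210** parameters for C = 2 and **7342** for C = 6, and the
spatial trace 257 → 255, 127, 125, 62, 60, 30, 28, 14, 12, 6, 4, 2 ends at
2×2×16 (flatten 64). Smaller inputs drop conv/pool pairs
(`max_conv_pairs()`) but keep the 32-unit penultimate layer.

The protocol: k-fold cross-validation in which every image is tested in
exactly one fold; per fold, a fixed validation set (25 images) and a
shuffled training pool whose growing prefixes form nested training subsets
(10, 20, …, 200 by default). For each fold × size a fresh network is
trained (Adam, cross-entropy, per-epoch flip/rotation augmentation, early
stopping with patience 50, best-epoch weights restored) and scored on the
fold's fixed test set — ROC-AUC for the binary task, macro F1 for the
six-class task with the training set balanced to 150 images per class by
augmentation.

## Worked example

```r
library(cytocurve)

spec <- build_network(257, 257, channels = 3, n_classes = 2)
count_parameters(spec)
#> [1] 7210

# a scaled study: 250 synthetic images at 65 px, 5 folds
cfg <- synthetic_config(leukocyte_classes("binary"), n_per_class = 125,
                        image_size = 65, effect_size = 1, seed = 401)
ds  <- generate_dataset(cfg)
pc  <- protocol_config(n_folds = 5, val_size = 25, sizes = c(10, 30, 60, 100),
                       max_epochs = 80, early_stop_patience = 20,
                       positive_class = "blast", seed = 402)
res <- run_learning_curve(ds, pc)
round(tapply(res$metric_value, res$train_size, mean), 3)
#>    10    30    60   100
#> 0.999 1.000 1.000 1.000
```

At full morphological effect size the synthetic classes are separable by
the nucleus:cytoplasm ratio alone, and the network reaches test ROC-AUC
near 1.0 from ten training images on — the learning curve saturates
immediately, and the mean at 30 images sits within 0.05 of the
large-sample value by a wide margin. The training-set size still shows up
inside the model: networks trained on 100 images separate the two classes
in their 32-dimensional penultimate layer more cleanly (higher silhouette
score) than networks trained on 10, which is what `saliency_map()`,
`lrp_map()` and `embed_penultimate()` are for. `summarize_box()` turns the
metric table into the boxplot summaries (type-7 quartiles, 1.5 IQR
whiskers).

The numbered scripts under `analysis/` run the whole study as a pipeline —
`01_simulate.R` (datasets + morphology validation),
`02_binary_learning_curve.R` (learning curve, mean ROC, boxplots),
`03_multiclass.R` (six-class F1 + confusion matrix),
`04_interpretability.R` (saliency/LRP maps), `05_embedding.R` (t-SNE +
silhouette separation) — writing tables and figures under `results/`.

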
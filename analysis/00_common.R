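# Shared settings for the analysis scripts.
#
# The study is run at a reduced but structurally identical scale to keep a
# full desktop re-run in minutes: 65 px images (the architecture drops to
# four conv/pool pairs, keeping the 32-unit penultimate layer), 250 images,
# 5 folds, nested sizes 10-100. The full-scale constants (257 px, 10 folds,
# sizes 10-200, patience 50) are the package defaults; swap them in here if
# you have the hours.

library(cytocurve)

MASTER_SEED <- 20260928L

binary_config <- synthetic_config(
  leukocyte_classes("binary"), n_per_class = 125, image_size = 65,
  effect_size = 1, distractors = TRUE, seed = derive_seed(MASTER_SEED, 1))

six_config <- synthetic_config(
  leukocyte_classes("six"), n_per_class = 45, image_size = 65,
  effect_size = 1, distractors = TRUE, seed = derive_seed(MASTER_SEED, 2))

binary_protocol <- protocol_config(
  n_folds = 5, val_size = 25, sizes = c(10, 30, 60, 100),
  max_epochs = 80, early_stop_patience = 20,
  metric = "roc_auc", positive_class = "blast",
  seed = derive_seed(MASTER_SEED, 3))

multiclass_protocol <- protocol_config(
  n_folds = 3, val_size = 25, sizes = 150, balance_target = 60,
  max_epochs = 60, early_stop_patience = 15,
  metric = "f1_macro", seed = derive_seed(MASTER_SEED, 4))

RESULTS <- "results"
MODELS <- file.path(RESULTS, "models")
dir.create(RESULTS, showWarnings = FALSE)
dir.create(MODELS, showWarnings = FALSE)
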
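#!/usr/bin/env Rscript
# Internal representation: t-SNE of the 32-dimensional penultimate layer for
# networks trained on 10 versus 100 images, evaluated on the fold's test
# images plus all pool images the respective model never saw. Class
# separation is quantified by the mean silhouette score.
# Run analysis/02_binary_learning_curve.R first.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

paths <- file.path(MODELS, c("binary_fold1_size10.rds",
                             "binary_fold1_size100.rds"))
if (!all(file.exists(paths)))
  stop("models not found; run analysis/02_binary_learning_curve.R first")
models <- lapply(paths, load_model)
names(models) <- c("10", "100")

ds <- generate_dataset(binary_config)
plan <- plan_folds(ds$sample_id, binary_protocol)
p <- plan[[1]]

embeddings <- list()
for (s in names(models)) {
  unseen <- setdiff(p$pool_ids, p$subsets[[s]])
  eval_set <- ds[c(p$test_ids, unseen)]
  act <- penultimate_activations(models[[s]], eval_set$images)
  sep_act <- separation_score(act, eval_set$labels)
  emb <- embed_penultimate(act, eval_set$labels, perplexity = 30,
                           seed = derive_seed(MASTER_SEED, 5),
                           sample_id = eval_set$sample_id)
  sep_2d <- separation_score(emb)
  cat(sprintf("size %3s: %d evaluation images, silhouette %.3f (32-D), %.3f (t-SNE 2-D)\n",
              s, nrow(emb), sep_act, sep_2d))
  emb$train_size <- as.integer(s)
  embeddings[[s]] <- emb
}
all_emb <- do.call(rbind, lapply(embeddings, as.data.frame))
write.csv(all_emb, file.path(RESULTS, "embedding_penultimate.csv"),
          row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  pl <- ggplot(all_emb, aes(x, y, color = label)) +
    geom_point(size = 1, alpha = 0.8) +
    facet_wrap(~train_size, scales = "free",
               labeller = label_both) +
    labs(title = "t-SNE of penultimate activations",
         x = NULL, y = NULL) +
    theme_minimal()
  ggsave(file.path(RESULTS, "embedding_penultimate.png"), pl,
         width = 7, height = 3.6, dpi = 150)
}
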
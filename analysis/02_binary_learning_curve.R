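#!/usr/bin/env Rscript
# The core experiment: how does lymphoblast-vs-rest test performance depend
# on the number of training images? For every fold and every nested training
# size a fresh network is trained from scratch and scored on the fold's
# fixed test set. Expect the ROC-AUC to saturate by a few tens of images.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

ds <- generate_dataset(binary_config)
t0 <- Sys.time()
res <- run_learning_curve(ds, binary_protocol, keep_models = TRUE,
                          verbose = TRUE)
cat(sprintf("learning curve done in %.1f min\n",
            as.numeric(Sys.time() - t0, units = "mins")))

write_learning_curve(res, file.path(RESULTS, "learning_curve_binary.csv"))

box <- summarize_box(res$metric_value, res$train_size)
write.csv(box[, -7], file.path(RESULTS, "learning_curve_binary_box.csv"),
          row.names = FALSE)
cat("\nper-size summary (median / quartiles):\n")
print(box[, 1:4])
means <- tapply(res$metric_value, res$train_size, mean)
sds <- tapply(res$metric_value, res$train_size, sd)
cat(sprintf("\nmean ROC-AUC at size %s: %.3f +/- %.3f\n",
            names(means), means, sds))

# fold-averaged ROC curve at the largest training size
plan <- attr(res, "plan"); models <- attr(res, "models")
largest <- as.character(max(binary_protocol$sizes))
curves <- lapply(seq_along(plan), function(f) {
  test <- ds[plan[[f]]$test_ids]
  roc_curve(predict_proba(models[[f]][[largest]], test$images)[, "blast"],
            test$labels == "blast")
})
mcurve <- mean_roc(curves)
cat(sprintf("\nfold-mean ROC at size %s: AUC of mean curve %.3f, mean of AUCs %.3f +/- %.3f\n",
            largest, mcurve$auc, mcurve$mean_auc, mcurve$sd_auc))
write.csv(data.frame(fpr = mcurve$fpr, tpr = mcurve$tpr),
          file.path(RESULTS, "mean_roc_binary.csv"), row.names = FALSE)

# keep fold-1 models at the smallest and largest sizes for the
# interpretability and embedding analyses
for (s in c("10", largest))
  save_model(models[[1]][[s]], file.path(MODELS, paste0("binary_fold1_size", s, ".rds")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(res, aes(factor(train_size), metric_value)) +
    geom_boxplot(fill = "grey85") +
    geom_jitter(width = 0.08, alpha = 0.6, size = 1) +
    labs(x = "training images", y = "test ROC-AUC",
         title = "Lymphoblast classification vs training-set size") +
    theme_minimal()
  ggsave(file.path(RESULTS, "learning_curve_binary.png"), p,
         width = 5, height = 3.4, dpi = 150)
  pr <- ggplot(data.frame(fpr = mcurve$fpr, tpr = mcurve$tpr),
               aes(fpr, tpr)) +
    geom_abline(linetype = 3) + geom_line(linewidth = 0.8) +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("Mean ROC over %d folds (size %s)", length(curves),
                         largest)) +
    theme_minimal()
  ggsave(file.path(RESULTS, "mean_roc_binary.png"), pr,
         width = 3.8, height = 3.6, dpi = 150)
}

write_manifest(file.path(RESULTS, "manifest_binary_curve.json"),
               binary_protocol, seed = MASTER_SEED,
               artifacts = list(curve = "results/learning_curve_binary.csv",
                                roc = "results/mean_roc_binary.csv"))
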
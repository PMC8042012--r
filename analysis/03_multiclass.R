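#!/usr/bin/env Rscript
# Six-class leukocyte classification. The training set is balanced to a
# fixed per-class size by flip/rotation augmentation before each training;
# performance is summarized by the macro F1-score (the test sets stay
# imbalanced) and a pooled confusion matrix with per-class counts.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

ds <- generate_dataset(six_config)
print(ds)

t0 <- Sys.time()
res <- run_learning_curve(ds, multiclass_protocol, keep_models = TRUE,
                          verbose = TRUE)
cat(sprintf("multiclass run done in %.1f min\n",
            as.numeric(Sys.time() - t0, units = "mins")))
write_learning_curve(res, file.path(RESULTS, "multiclass_f1.csv"))
cat(sprintf("\nmacro F1: %.3f +/- %.3f (n = %d folds)\n",
            mean(res$metric_value), sd(res$metric_value), nrow(res)))

# pooled confusion matrix over all folds at the (single) training size
plan <- attr(res, "plan"); models <- attr(res, "models")
size <- as.character(multiclass_protocol$sizes[1])
pred_all <- character(0); true_all <- character(0)
for (f in seq_along(plan)) {
  test <- ds[plan[[f]]$test_ids]
  probs <- predict_proba(models[[f]][[size]], test$images)
  pred_all <- c(pred_all,
                models[[f]][[size]]$class_order[max.col(probs, "first")])
  true_all <- c(true_all, as.character(test$labels))
}
cm <- confusion(pred_all, true_all, class_order = levels(ds$labels))
print(cm)
write.csv(cm$counts, file.path(RESULTS, "multiclass_confusion_counts.csv"))
write.csv(round(cm$row_percent, 2),
          file.path(RESULTS, "multiclass_confusion_percent.csv"))

write_manifest(file.path(RESULTS, "manifest_multiclass.json"),
               multiclass_protocol, seed = MASTER_SEED,
               artifacts = list(f1 = "results/multiclass_f1.csv",
                                confusion = "results/multiclass_confusion_counts.csv"))
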
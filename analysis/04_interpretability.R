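#!/usr/bin/env Rscript
# Where does the classifier look? Gradient saliency and layer-wise relevance
# propagation for networks trained on few (10) versus many (100) images.
# Run analysis/02_binary_learning_curve.R first; it leaves the two fold-1
# models under results/models/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

paths <- file.path(MODELS, c("binary_fold1_size10.rds",
                             "binary_fold1_size100.rds"))
if (!all(file.exists(paths)))
  stop("models not found; run analysis/02_binary_learning_curve.R first")
models <- lapply(paths, load_model)
names(models) <- c("10", "100")

ds <- generate_dataset(binary_config)
# one blast and one non-blast example, neither seen by the fold-1 models
plan <- plan_folds(ds$sample_id, binary_protocol)
test <- ds[plan[[1]]$test_ids]
pick <- c(which(test$labels == "blast")[1], which(test$labels == "nonblast")[1])

outdir <- file.path(RESULTS, "relevance")
dir.create(outdir, showWarnings = FALSE)
# fraction of attribution mass inside the central half of the frame: a crude
# localization index (the cell is centered; distractors are not)
central_mass <- function(v) {
  n <- nrow(v); q <- round(n / 4)
  sum(abs(v[(q + 1):(n - q), (q + 1):(n - q)])) / sum(abs(v))
}

for (i in pick) {
  img <- test$images[, , , i]
  id <- test$sample_id[i]
  png::writePNG(img, file.path(outdir, paste0(id, "_input.png")))
  for (s in names(models)) {
    sal <- saliency_map(models[[s]], img, target_class = "blast")
    lrp <- lrp_map(models[[s]], img, target_class = "blast")
    png::writePNG(render_relevance(sal),
                  file.path(outdir, sprintf("%s_size%s_saliency.png", id, s)))
    png::writePNG(render_relevance(lrp),
                  file.path(outdir, sprintf("%s_size%s_lrp.png", id, s)))
    cat(sprintf("%s | size %3s | logit %.3f | LRP sum %.3f (gap %.2f%%) | central saliency mass %.2f\n",
                id, s, lrp$explained_score, sum(lrp$values),
                100 * abs(sum(lrp$values) - lrp$explained_score) /
                  max(abs(lrp$explained_score), 1e-9),
                central_mass(sal$values)))
  }
}
cat("relevance maps written to", outdir, "\n")
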
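# Shared fixtures: everything is generated in code at test time.

# A tiny network that still exercises every layer kind.
tiny_spec <- function(size = 14, pairs = 2, filters = c(3, 4), hidden = 5,
                      n_classes = 2) {
  build_network(size, size, 3, n_classes, n_conv_pairs = pairs,
                filters = filters, hidden_units = hidden)
}

# Small synthetic dataset for protocol / training tests.
tiny_dataset <- function(n_per_class = 30, image_size = 36, effect_size = 1,
                         seed = 7, classes = leukocyte_classes("binary")) {
  generate_dataset(synthetic_config(classes, n_per_class,
                                    image_size = image_size,
                                    effect_size = effect_size,
                                    distractors = TRUE, seed = seed))
}

# Brute-force pairwise AUC oracle: P(score_pos > score_neg), ties 1/2.
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Central finite-difference gradient of the target-class logit with respect
# to the input pixels of a single image.
numeric_logit_gradient <- function(model, img, target, h = 1e-4) {
  g <- array(0, dim = dim(img))
  for (k in seq_along(img)) {
    xp <- img; xp[k] <- img[k] + h
    xm <- img; xm[k] <- img[k] - h
    g[k] <- (forward_cnn_logit(model, xp, target) -
             forward_cnn_logit(model, xm, target)) / (2 * h)
  }
  g
}

forward_cnn_logit <- function(model, img, target) {
  cytocurve:::forward_cnn(model, img)$logits[target, 1]
}
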
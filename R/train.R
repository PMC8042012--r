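#' Randomly augment one image
#'
#' Applies, independently: a horizontal flip with probability 0.5, a vertical
#' flip with probability 0.5, and a rotation by an angle drawn uniformly from
#' [0, 359] degrees (bilinear interpolation, constant fill, output size
#' preserved). The label of a sample is never touched. Any of the three
#' transforms can be forced for reproducible tests.
#'
#' @param img `H x W x C` array in `[0, 1]`.
#' @param hflip,vflip logical; `NULL` draws from the current RNG.
#' @param angle rotation in degrees; `NULL` draws uniformly from `[0, 359]`.
#' @param fill per-channel constant fill color for pixels rotated in from
#'   outside the frame; defaults to the per-channel median of the image
#'   border (a robust estimate of the background stain).
#' @return augmented array, same shape, clipped to `[0, 1]`.
#' @export
augment_image <- function(img, hflip = NULL, vflip = NULL, angle = NULL,
                          fill = NULL) {
  stopifnot(length(dim(img)) == 3)
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  hflip <- hflip %||% (runif(1) < 0.5)
  vflip <- vflip %||% (runif(1) < 0.5)
  angle <- angle %||% runif(1, 0, 359)
  if (is.null(fill)) fill <- border_fill(img)
  if (hflip) img <- img[, w:1, , drop = FALSE]
  if (vflip) img <- img[h:1, , , drop = FALSE]
  if (angle %% 360 != 0) {
    # rotate all channels in one call: shift so the fill color maps to zero
    shifted <- sweep(img, 3, fill)
    rot <- EBImage::rotate(shifted, angle, filter = "bilinear",
                           output.dim = c(h, w), bg.col = 0)
    img <- clip01(sweep(array(rot, dim = c(h, w, nc)), 3, fill, "+"))
  }
  img
}

# Per-channel median of the image border: robust background estimate used
# as the rotation fill when no explicit background color is configured.
border_fill <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  vapply(seq_len(dim(img)[3]), function(ch)
    median(c(img[1, , ch], img[h, , ch], img[, 1, ch], img[, w, ch])),
    numeric(1))
}

#' Balance a training set to a fixed per-class size by augmentation
#'
#' Classes below `target` keep all their originals and are topped up with
#' augmented copies of randomly chosen originals; classes above `target` are
#' randomly subsampled down to `target`. Augmented copies get sample ids of
#' the form `<ancestor>_aug<k>`, so provenance is auditable.
#'
#' @param train_set a `labeled_dataset`.
#' @param target images per class after balancing.
#' @param fill passed to [augment_image()].
#' @return a balanced `labeled_dataset` with an `ancestor_id` field.
#' @export
balance_by_augmentation <- function(train_set, target = 150L, fill = NULL) {
  labs <- train_set$labels
  counts <- table(labs)
  empty <- names(counts)[counts == 0]
  if (length(empty))
    stop("cannot balance: class '", empty[1], "' has no images")
  pieces_idx <- list(); aug_src <- integer(0)
  for (cl in levels(labs)) {
    idx <- which(labs == cl)
    if (length(idx) >= target) {
      pieces_idx[[cl]] <- sample(idx, target)
    } else {
      pieces_idx[[cl]] <- idx
      aug_src <- c(aug_src, sample(idx, target - length(idx), replace = TRUE))
    }
  }
  keep <- unlist(pieces_idx, use.names = FALSE)
  d <- dim(train_set$images)
  n_out <- length(keep) + length(aug_src)
  images <- array(0, dim = c(d[1:3], n_out))
  images[, , , seq_along(keep)] <- train_set$images[, , , keep]
  ids <- train_set$sample_id[keep]
  ancestors <- train_set$sample_id[keep]
  labels <- as.character(labs[keep])
  for (j in seq_along(aug_src)) {
    src <- aug_src[j]
    images[, , , length(keep) + j] <-
      augment_image(train_set$images[, , , src], fill = fill)
    ids <- c(ids, paste0(train_set$sample_id[src], "_aug", j))
    ancestors <- c(ancestors, train_set$sample_id[src])
    labels <- c(labels, as.character(labs[src]))
  }
  out <- labeled_dataset(images, factor(labels, levels = levels(labs)), ids,
                         config = train_set$config)
  out$ancestor_id <- ancestors
  out
}

#' Early-stopping rule on a validation-loss history
#'
#' Training halts once the best validation loss has not decreased for
#' `patience` consecutive epochs. Ties do not count as an improvement, so the
#' earliest epoch attaining the best loss is kept.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience epochs without improvement before stopping.
#' @return list with `stop_epoch` (last epoch that would be run, `NA` if the
#'   rule never fires within the history) and `best_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf; best_ep <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_ep <- e
    } else if (e - best_ep >= patience) {
      return(list(stop_epoch = e, best_epoch = best_ep))
    }
  }
  list(stop_epoch = NA_integer_, best_epoch = best_ep)
}

# One-hot matrix (K x N) from a factor, in the order of its levels.
onehot <- function(labels) {
  k <- nlevels(labels)
  y <- matrix(0, k, length(labels))
  y[cbind(as.integer(labels), seq_along(labels))] <- 1
  y
}

# Mean cross-entropy of probs (K x N) against one-hot y.
cross_entropy <- function(probs, y) {
  -mean(colSums(y * log(pmax(probs, 1e-12))))
}

.adam_init <- function(weights) {
  lapply(weights, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = array(0, dim(p$W) %||% length(p$W)), vW = array(0, dim(p$W) %||% length(p$W)),
         mb = numeric(length(p$b)), vb = numeric(length(p$b)))
  })
}

.adam_step <- function(weights, grads, state, t, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(weights)) {
    if (is.null(weights[[i]])) next
    g <- grads[[i]]
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    weights[[i]]$W <- weights[[i]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    weights[[i]]$b <- weights[[i]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(weights = weights, state = state)
}

#' Train a model with augmentation and early stopping
#'
#' Minimizes the (binary or categorical) cross-entropy with Adam. Each epoch
#' the training set is re-augmented on the fly (default: every image is
#' passed once through [augment_image()]; `augment_mode = "append"` instead
#' appends a random number of augmented copies while keeping the originals),
#' shuffled, and consumed in minibatches. Training stops when the validation
#' loss has not decreased for `patience` epochs or at `max_epochs`; the
#' weights of the best-validation epoch are restored.
#'
#' @param spec a `network_spec` (or an already initialized `cyto_model`).
#' @param train_set,val_set disjoint `labeled_dataset`s whose image shape
#'   matches the spec.
#' @param config a [protocol_config()]; fields used here: `learning_rate`,
#'   `batch_size`, `max_epochs`, `early_stop_patience`, `augment`,
#'   `augment_mode`, `background_color`.
#' @param seed integer seed covering initialization, augmentation and
#'   shuffling; identical seeds give identical trained weights.
#' @return a `cyto_model` with `history` (tibble of per-epoch train/val loss)
#'   and `best_epoch` filled in.
#' @export
train_model <- function(spec, train_set, val_set, config = protocol_config(),
                        seed = 1L) {
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("train and validation sets must be non-empty")
  if (length(intersect(train_set$sample_id, val_set$sample_id)))
    stop("train and validation sets overlap")
  model <- if (inherits(spec, "cyto_model")) spec else init_model(spec, seed)
  model$class_order <- levels(train_set$labels)
  y_tr_all <- onehot(train_set$labels)
  y_val <- onehot(val_set$labels)
  x_val <- val_set$images
  state <- .adam_init(model$weights)
  best <- list(loss = Inf, epoch = 0L, weights = model$weights)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  n <- length(train_set)
  # rotation fill per image, computed once (border median unless configured)
  fills <- if (config$augment) {
    if (!is.null(config$background_color)) {
      rep(list(config$background_color), n)
    } else {
      lapply(seq_len(n), function(j) border_fill(train_set$images[, , , j]))
    }
  }
  with_seed(derive_seed(seed, 7L), {
    t_step <- 0
    for (epoch in seq_len(config$max_epochs)) {
      if (config$augment && config$augment_mode == "append") {
        k <- sample(0:n, 1)
        src <- if (k > 0) sample(n, k, replace = TRUE) else integer(0)
        x_ep <- array(0, dim = c(dim(train_set$images)[1:3], n + k))
        x_ep[, , , seq_len(n)] <- train_set$images
        for (j in seq_along(src))
          x_ep[, , , n + j] <- augment_image(train_set$images[, , , src[j]],
                                             fill = fills[[src[j]]])
        y_ep <- cbind(y_tr_all, y_tr_all[, src, drop = FALSE])
      } else if (config$augment) {
        x_ep <- train_set$images
        for (j in seq_len(n))
          x_ep[, , , j] <- augment_image(train_set$images[, , , j],
                                         fill = fills[[j]])
        y_ep <- y_tr_all
      } else {
        x_ep <- train_set$images
        y_ep <- y_tr_all
      }
      m <- dim(x_ep)[4]
      ord <- sample(m)
      ep_loss <- 0
      for (start in seq(1, m, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1, m)]
        xb <- x_ep[, , , take, drop = FALSE]
        yb <- y_ep[, take, drop = FALSE]
        fwd <- forward_cnn(model, xb, cache = TRUE)
        ep_loss <- ep_loss + cross_entropy(fwd$probs, yb) * length(take)
        dlogits <- (fwd$probs - yb) / length(take)
        bw <- backward_cnn(model, fwd, dlogits)
        t_step <- t_step + 1
        upd <- .adam_step(model$weights, bw$grads, state, t_step,
                          config$learning_rate)
        model$weights <- upd$weights
        state <- upd$state
      }
      hist_tr <- c(hist_tr, ep_loss / m)
      val_probs <- forward_cnn(model, x_val)$probs
      vl <- cross_entropy(val_probs, y_val)
      hist_val <- c(hist_val, vl)
      if (vl < best$loss) {
        best <- list(loss = vl, epoch = epoch, weights = model$weights)
      } else if (epoch - best$epoch >= config$early_stop_patience) {
        break
      }
    }
  })
  model$weights <- best$weights
  model$best_epoch <- best$epoch
  model$history <- tibble::tibble(epoch = seq_along(hist_tr),
                                  train_loss = hist_tr, val_loss = hist_val)
  model$seed <- seed
  model
}
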
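#' Construct the sequential CNN specification
#'
#' Builds the fixed small sequential architecture used throughout the
#' package: `n_conv_pairs` pairs of a valid-padding 3x3 convolution followed
#' by 2x2/stride-2 max pooling, a flatten, one hidden dense layer (width 32
#' by default, the penultimate representation used for embedding), and a
#' softmax output. With the defaults (six pairs, filters 4, 8, 8, 8, 16, 16)
#' and a 257x257 RGB input the network has exactly 7210 parameters for two
#' classes and 7342 for six.
#'
#' Smaller inputs cannot pass six valid-convolution/pooling stages; for those,
#' reduce `n_conv_pairs` (see [max_conv_pairs()]). The filter schedule is
#' truncated accordingly.
#'
#' @param height,width input size in pixels.
#' @param channels number of input channels (3 for RGB).
#' @param n_classes number of output classes (>= 2).
#' @param n_conv_pairs number of convolution + pooling pairs (0--6).
#' @param filters integer vector of convolution filter counts, one per pair.
#' @param hidden_units width of the hidden dense layer; 0 omits it.
#' @return an object of class `network_spec`.
#' @examples
#' spec <- build_network(257, 257, 3, 2)
#' count_parameters(spec)  # 7210
#' @export
build_network <- function(height, width, channels = 3, n_classes = 2,
                          n_conv_pairs = 6,
                          filters = c(4L, 8L, 8L, 8L, 16L, 16L)[seq_len(n_conv_pairs)],
                          hidden_units = 32L) {
  stopifnot(height >= 1, width >= 1, channels >= 1, n_classes >= 2,
            n_conv_pairs >= 0, n_conv_pairs <= 6,
            length(filters) == n_conv_pairs)
  layers <- list()
  for (f in filters) {
    layers <- c(layers, list(
      list(kind = "conv", kernel = 3L, filters = as.integer(f),
           padding = "valid", activation = "relu"),
      list(kind = "pool", size = 2L, stride = 2L)))
  }
  layers <- c(layers, list(list(kind = "flatten")))
  if (hidden_units > 0) {
    layers <- c(layers, list(list(kind = "dense", units = as.integer(hidden_units),
                                  activation = "relu")))
  }
  layers <- c(layers, list(list(kind = "dense", units = as.integer(n_classes),
                                activation = "softmax")))
  spec <- structure(
    list(input_dim = c(as.integer(height), as.integer(width), as.integer(channels)),
         n_classes = as.integer(n_classes), layers = layers),
    class = "network_spec")
  spatial_trace(spec)  # errors if any stage underflows
  spec
}

#' Largest feasible number of convolution/pooling pairs for an input size
#'
#' @param height,width input size in pixels.
#' @param max_pairs upper bound on pairs (default 6, the full architecture).
#' @return integer number of pairs.
#' @export
max_conv_pairs <- function(height, width = height, max_pairs = 6L) {
  for (k in rev(seq_len(max_pairs))) {
    ok <- tryCatch({
      build_network(height, width, 3, 2, n_conv_pairs = k)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(as.integer(k))
  }
  stop("input ", height, "x", width, " too small for even one conv/pool pair")
}

#' Trace spatial dimensions through every layer
#'
#' Valid 3x3 convolution shrinks each spatial dimension by 2; 2x2/stride-2
#' pooling halves it with floor. Errors, naming the offending layer, if any
#' stage would produce a dimension below 1.
#'
#' @param spec a `network_spec`.
#' @return a tibble with one row per layer: `layer`, `kind`, `height`,
#'   `width`, `channels`, `units` (units is `NA` until the flatten).
#' @export
spatial_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  h <- spec$input_dim[1]; w <- spec$input_dim[2]; c <- spec$input_dim[3]
  units <- NA_integer_
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      h <- h - 2L; w <- w - 2L; c <- ly$filters
      if (h < 1 || w < 1)
        stop("spatial underflow at layer ", i, " (conv): input too small")
    } else if (ly$kind == "pool") {
      h <- h %/% 2L; w <- w %/% 2L
      if (h < 1 || w < 1)
        stop("spatial underflow at layer ", i, " (pool): input too small")
    } else if (ly$kind == "flatten") {
      units <- h * w * c
      h <- NA_integer_; w <- NA_integer_; c <- NA_integer_
    } else if (ly$kind == "dense") {
      units <- ly$units
    }
    rows[[i]] <- tibble::tibble(layer = i, kind = ly$kind, height = h,
                                width = w, channels = c, units = units)
  }
  do.call(rbind, rows)
}

#' Count trainable parameters of a network specification
#'
#' A convolution contributes `k^2 * c_in * c_out + c_out`, a dense layer
#' `n_in * n_out + n_out`; pooling and flatten contribute nothing.
#'
#' @param spec a `network_spec`.
#' @return integer parameter count.
#' @examples
#' count_parameters(build_network(257, 257, 3, 6))  # 7342
#' @export
count_parameters <- function(spec) {
  sum(vapply(.param_shapes(spec), function(s) {
    if (is.null(s)) 0L else as.integer(prod(s$W) + s$b)
  }, integer(1)))
}

# Per-layer parameter array shapes (NULL for layers without parameters).
.param_shapes <- function(spec) {
  c_in <- spec$input_dim[3]
  n_in <- NA_integer_
  tr <- spatial_trace(spec)
  shapes <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      shapes[[i]] <- list(W = c(3L, 3L, c_in, ly$filters), b = ly$filters)
      c_in <- ly$filters
    } else if (ly$kind == "flatten") {
      n_in <- tr$units[i]
    } else if (ly$kind == "dense") {
      shapes[[i]] <- list(W = c(n_in, ly$units), b = ly$units)
      n_in <- ly$units
    }
  }
  shapes
}

#' Initialize a model with seeded random weights
#'
#' Weights are drawn from a uniform fan-in-scaled distribution
#' (`U(-l, l)` with `l = sqrt(6 / fan_in)`); biases start at zero. The same
#' seed always yields bit-identical weights.
#'
#' @param spec a `network_spec`.
#' @param seed integer seed.
#' @return an (untrained) object of class `cyto_model`.
#' @export
init_model <- function(spec, seed = 1L) {
  shapes <- .param_shapes(spec)
  weights <- with_seed(seed, lapply(shapes, function(s) {
    if (is.null(s)) return(NULL)
    fan_in <- if (length(s$W) == 4) 9 * s$W[3] else s$W[1]
    lim <- sqrt(6 / fan_in)
    list(W = array(runif(prod(s$W), -lim, lim), dim = s$W),
         b = numeric(s$b))
  }))
  structure(list(spec = spec, weights = weights, history = NULL,
                 best_epoch = NA_integer_, class_order = NULL, seed = seed),
            class = "cyto_model")
}

# Promote a single image (H,W,C) to a batch (H,W,C,1).
.as_batch <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

.softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Forward pass. x: (H,W,C,N) array. Returns list(logits K x N, probs K x N,
# penultimate units x N, cache). Activation caches are kept only if
# cache = TRUE (needed for backprop / LRP).
forward_cnn <- function(model, x, cache = FALSE) {
  spec <- model$spec
  x <- .as_batch(x)
  if (!all(dim(x)[1:3] == spec$input_dim))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match model input ", paste(spec$input_dim, collapse = "x"))
  n <- dim(x)[4]
  a <- x
  caches <- if (cache) vector("list", length(spec$layers)) else NULL
  penult <- NULL
  logits <- NULL
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      p <- model$weights[[i]]
      z <- conv3x3_fw(a, p$W, p$b)
      if (cache) caches[[i]] <- list(input = a, z = z)
      a <- z * (z > 0)
    } else if (ly$kind == "pool") {
      res <- maxpool2_fw(a)
      if (cache) caches[[i]] <- list(idx = res$idx, in_dim = dim(a))
      a <- res$out
    } else if (ly$kind == "flatten") {
      if (cache) caches[[i]] <- list(in_dim = dim(a))
      dim(a) <- c(prod(dim(a)[1:3]), n)
    } else if (ly$kind == "dense") {
      p <- model$weights[[i]]
      z <- crossprod(p$W, a) + p$b
      if (cache) caches[[i]] <- list(input = a, z = z)
      if (ly$activation == "relu") {
        a <- z * (z > 0)
        penult <- a
      } else if (ly$activation == "softmax") {
        logits <- z
        a <- .softmax_cols(z)
      } else {
        a <- z
        logits <- z
      }
    }
  }
  list(logits = logits, probs = a, penultimate = penult, cache = caches)
}

# Backward pass from a gradient on the logits (K x N). Returns per-layer
# parameter gradients (same structure as model$weights) and, if requested,
# the gradient with respect to the input batch.
backward_cnn <- function(model, fwd, dlogits, input_grad = FALSE) {
  spec <- model$spec
  caches <- fwd$cache
  grads <- vector("list", length(spec$layers))
  da <- dlogits
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$kind == "dense") {
      cc <- caches[[i]]
      dz <- if (ly$activation == "relu") da * (cc$z > 0) else da
      grads[[i]] <- list(W = cc$input %*% t(dz), b = rowSums(dz))
      da <- model$weights[[i]]$W %*% dz
    } else if (ly$kind == "flatten") {
      dim(da) <- caches[[i]]$in_dim
    } else if (ly$kind == "pool") {
      cc <- caches[[i]]
      da <- maxpool2_bw(cc$idx, da, as.integer(cc$in_dim))
    } else if (ly$kind == "conv") {
      cc <- caches[[i]]
      dz <- da * (cc$z > 0)
      bw <- conv3x3_bw(cc$input, model$weights[[i]]$W, dz)
      grads[[i]] <- list(W = bw$gw, b = bw$gb)
      da <- bw$gx
    }
  }
  list(grads = grads, gx = if (input_grad) da else NULL)
}

#' Class probabilities for a batch of images
#'
#' @param model a `cyto_model`.
#' @param x an `(H, W, C, N)` array or a single `(H, W, C)` image.
#' @return an `N x n_classes` matrix of softmax probabilities (rows sum
#'   to 1), with column names taken from the model's class order if known.
#' @export
predict_proba <- function(model, x) {
  p <- t(forward_cnn(model, x)$probs)
  if (!is.null(model$class_order)) colnames(p) <- model$class_order
  p
}

#' Activations of the penultimate (hidden dense) layer
#'
#' The 32-dimensional representation used for t-SNE embedding and class
#' separation scoring.
#'
#' @inheritParams predict_proba
#' @return an `N x units` matrix of post-rectifier activations.
#' @export
penultimate_activations <- function(model, x) {
  pen <- forward_cnn(model, x)$penultimate
  if (is.null(pen)) stop("model has no hidden dense layer")
  t(pen)
}

#' @export
print.network_spec <- function(x, ...) {
  tr <- spatial_trace(x)
  cat("Sequential CNN: input ", paste(x$input_dim, collapse = "x"),
      ", ", x$n_classes, " classes, ", count_parameters(x), " parameters\n",
      sep = "")
  shapes <- .param_shapes(x)
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    out <- if (!is.na(tr$height[i])) {
      paste0(tr$height[i], "x", tr$width[i], "x", tr$channels[i])
    } else paste0(tr$units[i])
    np <- if (is.null(shapes[[i]])) 0 else prod(shapes[[i]]$W) + shapes[[i]]$b
    lab <- switch(ly$kind,
                  conv = paste0("conv 3x3/", ly$filters, " (", ly$activation, ")"),
                  pool = "maxpool 2x2",
                  flatten = "flatten",
                  dense = paste0("dense ", ly$units, " (", ly$activation, ")"))
    cat(sprintf("  %2d  %-22s -> %-12s %6d params\n", i, lab, out, np))
  }
  invisible(x)
}

#' @export
print.cyto_model <- function(x, ...) {
  cat("cyto_model (", if (is.null(x$history)) "untrained" else
    paste0("trained, best epoch ", x$best_epoch), ")\n", sep = "")
  print(x$spec)
  invisible(x)
}

#' Save / load a model (weights + JSON spec)
#'
#' Weights go into an RDS container next to a human-readable JSON copy of the
#' layer specification.
#'
#' @param model a `cyto_model`.
#' @param path file path for the weights (`.rds`); the spec is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(input_dim = model$spec$input_dim, n_classes = model$spec$n_classes,
         layers = model$spec$layers, n_parameters = count_parameters(model$spec)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
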
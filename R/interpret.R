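sign0 <- function(z) ifelse(z >= 0, 1, -1)

.relevance_map <- function(values, target_class, method) {
  structure(list(values = values, target_class = target_class,
                 method = method), class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(x$method, "map for class", x$target_class, "-",
      paste(dim(x$values), collapse = "x"),
      sprintf("(sum %.4g, max |v| %.4g)\n", sum(x$values),
              max(abs(x$values))))
  invisible(x)
}

#' Gradient saliency map
#'
#' Per-pixel relevance as the absolute gradient of the pre-softmax score of
#' the target class with respect to the input, reduced over color channels
#' by the maximum (default) or the sum of absolute values. Values are
#' non-negative; brighter means a larger influence on the class score.
#'
#' @param model a trained `cyto_model`.
#' @param sample an `image_sample`, or a bare `H x W x C` array.
#' @param target_class class index (1-based) or class label.
#' @param reduce channel reduction, `"max_abs"` or `"sum_abs"`.
#' @return a `relevance_map` with non-negative `H x W` values.
#' @export
saliency_map <- function(model, sample, target_class = 1L,
                         reduce = c("max_abs", "sum_abs")) {
  reduce <- match.arg(reduce)
  x <- if (inherits(sample, "image_sample")) sample$pixels else sample
  tc <- .resolve_class(model, target_class)
  fwd <- forward_cnn(model, x, cache = TRUE)
  dlogits <- matrix(0, model$spec$n_classes, 1)
  dlogits[tc, 1] <- 1
  g <- backward_cnn(model, fwd, dlogits, input_grad = TRUE)$gx
  g <- abs(array(g, dim = dim(g)[1:3]))
  vals <- if (reduce == "max_abs") apply(g, c(1, 2), max) else
    apply(g, c(1, 2), sum)
  .relevance_map(vals, tc, "saliency")
}

.resolve_class <- function(model, target_class) {
  if (is.character(target_class)) {
    if (is.null(model$class_order) || !(target_class %in% model$class_order))
      stop("unknown class '", target_class, "'")
    return(match(target_class, model$class_order))
  }
  tc <- as.integer(target_class)
  if (tc < 1 || tc > model$spec$n_classes)
    stop("invalid class index ", tc)
  tc
}

#' Layer-wise relevance propagation map
#'
#' Decomposes the pre-softmax score of the target class into signed
#' per-pixel relevances. Dense and convolution layers use the stabilized
#' epsilon rule (`R_i = sum_j x_i w_ij / (z_j + eps * sign(z_j)) R_j`); the
#' `"alpha_beta"` rule with `alpha = 1, beta = 0` (positive contributions
#' only) is available as an alternative. Max-pooling routes relevance to the
#' winning input; the input relevance is summed over color channels. With
#' zero biases the total relevance is conserved up to epsilon leakage;
#' nonzero biases absorb part of it.
#'
#' @inheritParams saliency_map
#' @param rule `"epsilon"` or `"alpha_beta"`.
#' @param epsilon stabilizer added to each denominator.
#' @return a `relevance_map` with signed `H x W` values; positive pixels
#'   support the target class, negative pixels speak against it.
#' @export
lrp_map <- function(model, sample, target_class = 1L,
                    rule = c("epsilon", "alpha_beta"), epsilon = 1e-6) {
  rule <- match.arg(rule)
  x <- if (inherits(sample, "image_sample")) sample$pixels else sample
  tc <- .resolve_class(model, target_class)
  fwd <- forward_cnn(model, x, cache = TRUE)
  spec <- model$spec
  R <- matrix(0, spec$n_classes, 1)
  R[tc, 1] <- fwd$logits[tc, 1]
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    cc <- fwd$cache[[i]]
    if (ly$kind == "dense") {
      W <- model$weights[[i]]$W
      if (rule == "alpha_beta") {
        Wp <- pmax(W, 0)
        z <- crossprod(Wp, cc$input)
        s <- R / (z + epsilon)
        R <- cc$input * (Wp %*% s)
      } else {
        s <- R / (cc$z + epsilon * sign0(cc$z))
        R <- cc$input * (model$weights[[i]]$W %*% s)
      }
    } else if (ly$kind == "flatten") {
      dim(R) <- cc$in_dim
    } else if (ly$kind == "pool") {
      R <- maxpool2_bw(cc$idx, R, as.integer(cc$in_dim))
    } else if (ly$kind == "conv") {
      W <- model$weights[[i]]$W
      if (rule == "alpha_beta") {
        Wp <- pmax(W, 0)
        z <- conv3x3_fw(cc$input, Wp, numeric(dim(W)[4]))
        s <- R / (z + epsilon)
        R <- cc$input * conv3x3_bw(cc$input, Wp, s)$gx
      } else {
        s <- R / (cc$z + epsilon * sign0(cc$z))
        R <- cc$input * conv3x3_bw(cc$input, W, s)$gx
      }
    }
  }
  vals <- apply(array(R, dim = dim(R)[1:3]), c(1, 2), sum)
  out <- .relevance_map(vals, tc, "lrp")
  out$explained_score <- fwd$logits[tc, 1]
  out
}

#' Exact t-SNE embedding to two dimensions
#'
#' Classic exact (O(n^2)) t-distributed stochastic neighbor embedding:
#' Gaussian input affinities calibrated per point to the target perplexity
#' by bisection, symmetrized, then a Student-t low-dimensional similarity
#' fitted by gradient descent with momentum, adaptive gains, and early
#' exaggeration. Deterministic for a fixed seed.
#'
#' @param x numeric matrix, one row per sample.
#' @param perplexity effective neighborhood size; must be `< nrow(x)`.
#' @param n_iter gradient-descent iterations.
#' @param seed seed for the random initialization.
#' @param eta learning rate.
#' @return `n x 2` matrix of coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, n_iter = 500L, seed = 1L,
                       eta = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 samples to embed")
  if (perplexity >= n) stop("perplexity must be smaller than the sample count")
  D2 <- as.matrix(dist(x))^2
  if (all(D2 < 1e-24)) {
    warning("degenerate input: all rows identical; returning zeros")
    out <- matrix(0, n, 2)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(n_iter)) {
      Peff <- if (iter <= 100) P * 12 else P  # early exaggeration
      D2y <- as.matrix(dist(Y))^2
      num <- 1 / (1 + D2y); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      PQ <- (Peff - Q) * num
      grad <- 4 * (diag(rowSums(PQ)) %*% Y - PQ %*% Y)
      mom <- if (iter < 250) 0.5 else 0.8
      gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8),
                    0.01)
      inc <- mom * inc - eta * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Embed penultimate-layer activations in two dimensions
#'
#' Reduces the 32-dimensional hidden representation to 2-D with
#' [tsne_embed()] for visual assessment of class separation.
#'
#' @param activations `n x d` matrix (see [penultimate_activations()]).
#' @param labels per-sample class labels.
#' @param perplexity,seed,n_iter embedding settings.
#' @param sample_id optional ids carried into the result.
#' @return an `embedding2d`: tibble with `sample_id`, `x`, `y`, `label`,
#'   plus attributes `perplexity` and `seed`.
#' @export
embed_penultimate <- function(activations, labels, perplexity = 30,
                              seed = 1L, n_iter = 500L, sample_id = NULL) {
  stopifnot(nrow(activations) == length(labels))
  coords <- tsne_embed(activations, perplexity = perplexity, seed = seed,
                       n_iter = n_iter)
  out <- tibble::tibble(
    sample_id = sample_id %||% sprintf("sample_%04d", seq_len(nrow(coords))),
    x = coords[, 1], y = coords[, 2], label = as.factor(labels))
  class(out) <- c("embedding2d", class(out))
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  attr(out, "degenerate") <- isTRUE(attr(coords, "degenerate"))
  out
}

#' Silhouette-based class separation score
#'
#' Mean silhouette coefficient (Euclidean distance) of the samples grouped
#' by their class labels: near 1 for tight, well-separated classes, near 0
#' (or below) for overlapping ones. Quantifies cluster separation in an
#' embedding or directly on penultimate activations.
#'
#' @param x coordinate or activation matrix (or an `embedding2d`).
#' @param labels class labels; at least two classes with two samples each.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
separation_score <- function(x, labels = NULL) {
  if (inherits(x, "embedding2d")) {
    labels <- labels %||% x$label
    x <- cbind(x$x, x$y)
  }
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("separation score needs at least two classes")
  if (any(table(labels) < 2))
    stop("every class needs at least two samples")
  sil <- cluster::silhouette(as.integer(labels), dist(x))
  mean(sil[, "sil_width"])
}

#' Render a relevance map to an RGB overlay array
#'
#' Saliency maps use monotone brightness; LRP maps use a diverging blue
#' (negative) to red (positive) colormap, symmetric about zero.
#'
#' @param map a `relevance_map`.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
render_relevance <- function(map) {
  v <- map$values
  out <- array(0, dim = c(dim(v), 3))
  if (map$method == "saliency") {
    b <- v / max(v, 1e-12)
    out[, , 1] <- b; out[, , 2] <- b; out[, , 3] <- b
  } else {
    m <- max(abs(v), 1e-12)
    pos <- pmax(v, 0) / m
    neg <- pmax(-v, 0) / m
    out[, , 1] <- 1 - neg          # red channel drops where negative
    out[, , 2] <- 1 - pos - neg    # green drops everywhere colored
    out[, , 3] <- 1 - pos          # blue drops where positive
  }
  clip01(out)
}
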
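test_that("parameter accounting reproduces the published network totals", {
  expect_identical(count_parameters(build_network(257, 257, 3, 2)), 7210L)
  expect_identical(count_parameters(build_network(257, 257, 3, 6)), 7342L)
  # input-size change only moves the flatten width: 400 px -> 13354
  expect_identical(count_parameters(build_network(400, 400, 3, 2)), 13354L)
})

test_that("per-layer parameter contributions follow k2*cin*cout + cout", {
  spec <- build_network(257, 257, 3, 2)
  shapes <- cytocurve:::.param_shapes(spec)
  sizes <- vapply(shapes, function(s)
    if (is.null(s)) 0L else as.integer(prod(s$W) + s$b), integer(1))
  expect_identical(sizes[1], 112L)              # 3x3, 3 -> 4 channels
  expect_identical(sizes[length(sizes)], 66L)   # 32 -> 2 output
  expect_identical(sum(sizes), 7210L)
})

test_that("spatial trace follows the valid-conv / floor-pool recurrence", {
  tr <- spatial_trace(build_network(257, 257, 3, 2))
  conv_pool <- tr[tr$kind %in% c("conv", "pool"), ]
  expect_equal(conv_pool$height,
               c(255, 127, 125, 62, 60, 30, 28, 14, 12, 6, 4, 2))
  expect_equal(tr$units[tr$kind == "flatten"], 64)  # 2 * 2 * 16
  tr400 <- spatial_trace(build_network(400, 400, 3, 2))
  expect_equal(min(tr400$height, na.rm = TRUE), 4)
  expect_equal(tr400$units[tr400$kind == "flatten"], 256)
  expect_error(build_network(128, 128, 3, 2), "underflow")
})

test_that("hidden dense width is 32 and reduced-depth variants stay valid", {
  spec <- build_network(65, 65, 3, 2, n_conv_pairs = 4)
  dense <- Filter(function(l) l$kind == "dense", spec$layers)
  expect_equal(dense[[1]]$units, 32)
  expect_equal(max_conv_pairs(257), 6L)
  expect_equal(max_conv_pairs(65), 4L)
})

test_that("weight initialization is seeded and deterministic", {
  spec <- tiny_spec()
  m1 <- init_model(spec, 99)
  m2 <- init_model(spec, 99)
  m3 <- init_model(spec, 100)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))
  expect_true(all(vapply(Filter(Negate(is.null), m1$weights),
                         function(p) all(p$b == 0), logical(1))))
})

test_that("softmax rows sum to one for arbitrary inputs", {
  m <- init_model(tiny_spec(), 3)
  set.seed(1)
  x <- array(rnorm(14 * 14 * 3 * 7), dim = c(14, 14, 3, 7))
  p <- predict_proba(m, x)
  expect_equal(dim(p), c(7, 2))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
})

test_that("penultimate activations have the hidden width and zero out on zero input", {
  spec <- build_network(65, 65, 3, 2, n_conv_pairs = 4)
  m <- init_model(spec, 5)
  x <- array(0, dim = c(65, 65, 3, 2))
  act <- penultimate_activations(m, x)
  expect_equal(dim(act), c(2, 32))
  expect_true(all(act == 0))  # zero input, zero biases, rectifiers
})

test_that("penultimate activations match a hand computation on a bare dense model", {
  spec <- build_network(2, 2, 1, 2, n_conv_pairs = 0, hidden_units = 3)
  m <- init_model(spec, 1)
  W1 <- matrix(c(0.5, -1, 0.25, 2, 1, -0.5, 0, 1, 0.75, -0.25, 0.5, 1), 4, 3)
  m$weights[[2]] <- list(W = W1, b = c(0.1, -0.2, 0))
  x <- array(c(1, 2, 3, 4), dim = c(2, 2, 1))
  expected <- pmax(as.vector(t(W1) %*% c(1, 2, 3, 4)) + c(0.1, -0.2, 0), 0)
  expect_equal(as.vector(penultimate_activations(m, x)), expected)
})

test_that("backpropagated gradients match finite differences", {
  spec <- tiny_spec()
  m <- init_model(spec, 42)
  set.seed(9)
  x <- array(runif(14 * 14 * 3 * 2), dim = c(14, 14, 3, 2))
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  fwd <- cytocurve:::forward_cnn(m, x, cache = TRUE)
  bw <- cytocurve:::backward_cnn(m, fwd, (fwd$probs - y) / 2, input_grad = TRUE)
  loss_at <- function(model) {
    cytocurve:::cross_entropy(cytocurve:::forward_cnn(model, x)$probs, y)
  }
  h <- 1e-5
  for (li in which(!vapply(m$weights, is.null, logical(1)))) {
    v <- m$weights[[li]]$W
    idx <- seq_len(min(length(v), 12))
    num <- vapply(idx, function(k) {
      mp <- m; mp$weights[[li]]$W[k] <- v[k] + h
      mm <- m; mm$weights[[li]]$W[k] <- v[k] - h
      (loss_at(mp) - loss_at(mm)) / (2 * h)
    }, numeric(1))
    expect_equal(as.vector(bw$grads[[li]]$W)[idx], num, tolerance = 1e-6)
  }
})
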
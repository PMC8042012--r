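test_that("saliency maps match central finite differences of the class logit", {
  spec <- tiny_spec(size = 12, pairs = 1, filters = 3, hidden = 4)
  m <- init_model(spec, 17)
  set.seed(23)
  img <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  for (target in 1:2) {
    sal <- saliency_map(m, img, target_class = target)
    num <- abs(numeric_logit_gradient(m, img, target))
    expect_equal(sal$values, apply(num, c(1, 2), max),
                 tolerance = 1e-4 * max(num))
    expect_true(all(sal$values >= 0))
    sal_sum <- saliency_map(m, img, target, reduce = "sum_abs")
    expect_equal(sal_sum$values, apply(num, c(1, 2), sum),
                 tolerance = 1e-4 * max(num))
  }
  expect_error(saliency_map(m, img, target_class = 5), "invalid class")
})

test_that("a model whose output ignores the input has a zero saliency map", {
  spec <- tiny_spec(size = 12, pairs = 1, filters = 3, hidden = 4)
  m <- init_model(spec, 2)
  last <- length(m$weights)
  m$weights[[last]]$W[] <- 0  # logits constant in the input
  set.seed(1)
  img <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  expect_true(all(saliency_map(m, img, 1)$values == 0))
})

test_that("LRP on a single linear layer recovers the x_i * w_i decomposition", {
  spec <- build_network(2, 2, 1, 2, n_conv_pairs = 0, hidden_units = 0)
  m <- init_model(spec, 1)
  W <- matrix(c(0.5, -1, 2, 0.25, 1, -0.5, 0.75, -0.25), 4, 2)
  m$weights[[2]] <- list(W = W, b = c(0, 0))
  x <- array(c(1, -2, 3, 0.5), dim = c(2, 2, 1))
  map <- lrp_map(m, x, target_class = 1, epsilon = 1e-9)
  expected <- matrix(as.vector(x) * W[, 1], 2, 2)
  expect_equal(map$values, expected, tolerance = 1e-6)
  expect_equal(sum(map$values), map$explained_score, tolerance = 1e-6)
})

test_that("LRP conserves relevance through a zero-bias network", {
  spec <- tiny_spec(size = 14, pairs = 2, filters = c(3, 4), hidden = 6)
  set.seed(33)
  for (rep in 1:5) {
    m <- init_model(spec, 100 + rep)  # biases are zero at initialization
    img <- array(runif(14 * 14 * 3), dim = c(14, 14, 3))
    target <- which.max(abs(cytocurve:::forward_cnn(m, img)$logits))
    map <- lrp_map(m, img, target_class = target)
    expect_equal(sum(map$values), map$explained_score,
                 tolerance = 0.01 * abs(map$explained_score))
  }
})

test_that("LRP of a zero input with zero biases is a zero map", {
  spec <- tiny_spec(size = 12, pairs = 1, filters = 3, hidden = 4)
  m <- init_model(spec, 3)
  img <- array(0, dim = c(12, 12, 3))
  map <- lrp_map(m, img, 1)
  expect_true(all(map$values == 0))
})

test_that("the alpha-beta rule yields only positively-driven relevance", {
  spec <- tiny_spec(size = 12, pairs = 1, filters = 3, hidden = 4)
  m <- init_model(spec, 11)
  set.seed(5)
  img <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  map <- lrp_map(m, img, 1, rule = "alpha_beta")
  expect_true(all(map$values >= -1e-12))  # inputs and kept weights are >= 0
})

test_that("t-SNE embedding is seeded, separates blobs, and checks preconditions", {
  set.seed(50)
  blob1 <- matrix(rnorm(30 * 32, mean = 0), 30, 32)
  blob2 <- matrix(rnorm(30 * 32, mean = 20 / sqrt(32)), 30, 32)
  x <- rbind(blob1, blob2)
  labels <- rep(c("a", "b"), each = 30)
  e1 <- embed_penultimate(x, labels, perplexity = 10, seed = 4, n_iter = 300)
  e2 <- embed_penultimate(x, labels, perplexity = 10, seed = 4, n_iter = 300)
  expect_identical(e1$x, e2$x)
  expect_equal(nrow(e1), 60)
  expect_gt(separation_score(e1), 0.5)
  expect_error(tsne_embed(x[1:4, ], perplexity = 30), "at least 5")
  expect_error(tsne_embed(x[1:10, ], perplexity = 30), "perplexity")
  # degenerate input: flagged, zeros
  expect_warning(z <- tsne_embed(matrix(1, 10, 4), perplexity = 3),
                 "degenerate")
  expect_true(all(z == 0))
})

test_that("separation score matches a hand-computed silhouette", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c("a", "a", "b", "b")
  a_i <- 1                                  # within-class distance
  b_i <- (10 + sqrt(101)) / 2               # mean distance to other class
  expected <- (b_i - a_i) / b_i             # same for all four points
  expect_equal(separation_score(pts, labels), expected, tolerance = 1e-12)
  # coincident classes carry no structure
  set.seed(6)
  xx <- matrix(rnorm(40), 20, 2)
  expect_lt(separation_score(xx, rep(c("a", "b"), 10)), 0.2)
  expect_error(separation_score(pts, rep("a", 4)), "two classes")
  expect_error(separation_score(pts, c("a", "b", "b", "b")), "two samples")
})

test_that("relevance maps render to valid RGB overlays", {
  v <- matrix(c(-1, 0, 0.5, 1), 2, 2)
  lrp <- cytocurve:::.relevance_map(v, 1, "lrp")
  img <- render_relevance(lrp)
  expect_equal(dim(img), c(2, 2, 3))
  expect_true(all(img >= 0 & img <= 1))
  # positive pixel redder than blue; negative pixel bluer than red
  expect_gt(img[2, 2, 1], img[2, 2, 3])
  expect_gt(img[1, 1, 3], img[1, 1, 1])
  sal <- cytocurve:::.relevance_map(abs(v), 1, "saliency")
  s <- render_relevance(sal)
  expect_equal(s[, , 1], s[, , 2])
})
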
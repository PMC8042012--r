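test_that("roc_auc equals the brute-force pairwise oracle on random instances", {
  set.seed(100)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)  # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc handles the canonical hand cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), c(rep(1, 5), rep(0, 5))), 0.5)
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "undefined")
})

test_that("roc_auc complements under label swap and matches the curve area", {
  set.seed(42)
  scores <- runif(30)  # all distinct almost surely
  labels <- runif(30) > 0.5
  expect_equal(roc_auc(scores, labels) + roc_auc(scores, !labels), 1)
  cv <- roc_curve(scores, labels)
  expect_equal(cv$auc, roc_auc(scores, labels), tolerance = 1e-12)
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[length(cv$fpr)], 1)
  expect_equal(cv$tpr[length(cv$tpr)], 1)
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:20) {
    scores <- round(runif(25), 2)
    labels <- runif(25) > 0.4
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("mean ROC vertically averages fold curves", {
  set.seed(1)
  scores <- runif(40); labels <- runif(40) > 0.5
  cv <- roc_curve(scores, labels)
  m1 <- mean_roc(list(cv))
  # linear interpolation cuts the staircase corners: identity holds up to
  # one half-step per negative sample
  expect_lt(abs(m1$auc - cv$auc), 1 / (2 * sum(!labels)) + 0.01)
  expect_equal(m1$mean_auc, cv$auc)
  m2 <- mean_roc(list(cv, cv))
  expect_equal(m2$tpr, m1$tpr)
  # a perfect and a chance-level straight-line curve average to AUC 0.75
  perfect <- structure(list(thresholds = c(Inf, 1, 0), fpr = c(0, 0, 1),
                            tpr = c(0, 1, 1), auc = 1), class = "roc_curve")
  chance <- structure(list(thresholds = c(Inf, 0), fpr = c(0, 1),
                           tpr = c(0, 1), auc = 0.5), class = "roc_curve")
  mm <- mean_roc(list(perfect, chance))
  expect_equal(mm$auc, 0.75, tolerance = 0.01)
  expect_equal(mm$mean_auc, 0.75)
})

test_that("macro F1 matches hand-computed worked examples", {
  expect_equal(f1_macro(c("A", "B", "C"), c("A", "B", "C")), 1.0)
  # per-class F1: A = 0.5, B = 0.8, C = 2/3 -> mean = 59/90
  truth <- c("A", "A", "B", "B", "C", "C")
  pred <- c("A", "B", "B", "B", "C", "A")
  expect_equal(f1_macro(pred, truth), 59 / 90, tolerance = 1e-4)
  expect_equal(f1_macro(c("B", "A"), c("A", "B")), 0.0)
  expect_error(f1_macro(character(0), character(0)), "empty")
})

test_that("macro F1 is invariant to sample order and consistent relabeling", {
  set.seed(9)
  truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- sample(c("A", "B", "C"), 60, replace = TRUE)
  base <- f1_macro(pred, truth)
  perm <- sample(60)
  expect_equal(f1_macro(pred[perm], truth[perm]), base)
  relab <- c(A = "x", B = "y", C = "z")
  expect_equal(f1_macro(relab[pred], relab[truth]), base)
})

test_that("confusion matrices count, percentage and flag empty rows", {
  cm <- confusion(c("A", "B", "B"), c("A", "A", "B"),
                  class_order = c("A", "B"))
  expect_equal(cm$counts["A", ], c(A = 1L, B = 1L))
  expect_equal(cm$row_percent["A", ], c(A = 50, B = 50))
  expect_equal(cm$row_percent["B", ], c(A = 0, B = 100))
  expect_equal(unname(cm$per_class_n), c(2, 1))
  expect_true(all(abs(rowSums(cm$row_percent) - 100) < 1e-9))
  # perfect prediction -> identity row percentages
  cm2 <- confusion(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_equal(unname(diag(cm2$row_percent)), c(100, 100))
  # class absent from the truth -> NA row, not 0/0
  cm3 <- confusion(c("A", "A"), c("A", "A"), class_order = c("A", "B"))
  expect_true(all(is.na(cm3$row_percent["B", ])))
  expect_error(confusion(c("A", "Z"), c("A", "A"), c("A", "B")), "Z")
})

test_that("box summaries use interpolated quartiles and 1.5 IQR fences", {
  s <- summarize_box(c(0.5, 0.7, 0.8, 0.9, 0.95))
  expect_equal(s$median, 0.8)
  expect_equal(s$q1, 0.7)
  expect_equal(s$q3, 0.9)
  expect_length(s$outliers[[1]], 0)
  # constant data collapses the box
  s2 <- summarize_box(rep(0.6, 8))
  expect_equal(s2$median, 0.6)
  expect_equal(s2$whisker_low, 0.6)
  expect_equal(s2$whisker_high, 0.6)
  # 0.1 lies below q1 - 1.5 IQR of (0.1, 0.8, 0.81, 0.82, 0.83)
  s3 <- summarize_box(c(0.1, 0.8, 0.81, 0.82, 0.83))
  expect_equal(s3$outliers[[1]], 0.1)
  expect_equal(s3$whisker_low, 0.8)
  # grouped by training size
  g <- summarize_box(c(1, 2, 3, 10, 20, 30), train_size = rep(c(10, 20), each = 3))
  expect_equal(g$train_size, c(10, 20))
  expect_equal(g$median, c(2, 20))
})
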
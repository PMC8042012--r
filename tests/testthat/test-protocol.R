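test_that("250 samples split into ten disjoint covering test sets with nested pools", {
  ids <- sprintf("img_%03d", 1:250)
  cfg <- protocol_config(n_folds = 10, val_size = 25,
                         sizes = seq(10, 200, 10), seed = 5)
  plan <- plan_folds(ids, cfg)
  expect_silent(validate_fold_plan(plan, ids))
  expect_length(plan, 10)
  for (p in plan) {
    expect_length(p$test_ids, 25)
    expect_length(p$val_ids, 25)
    expect_length(p$pool_ids, 200)
    expect_equal(as.integer(names(p$subsets)), seq(10, 200, 10))
    expect_equal(vapply(p$subsets, length, integer(1)),
                 setNames(seq(10, 200, 10), seq(10, 200, 10)))
    # strict nesting
    for (j in 2:length(p$subsets))
      expect_true(all(p$subsets[[j - 1]] %in% p$subsets[[j]]))
    # test/val/pool partition the ids
    expect_setequal(c(p$test_ids, p$val_ids, p$pool_ids), ids)
  }
  # every id tested exactly once
  expect_setequal(unlist(lapply(plan, `[[`, "test_ids")), ids)
  # deterministic under the seed
  expect_identical(plan_folds(ids, cfg), plan)
})

test_that("fold planning rejects insufficient samples", {
  cfg <- protocol_config(n_folds = 5, val_size = 10, sizes = c(50))
  expect_error(plan_folds(sprintf("s%02d", 1:60), cfg), "configuration error")
})

test_that("balanced test sets are class-balanced and disjoint across folds", {
  ids <- sprintf("s%03d", 1:300)
  labels <- factor(rep(c("blast", "nonblast"), each = 150))
  cfg <- protocol_config(n_folds = 3, test_size = 40, val_size = 20,
                         sizes = c(10, 30), balanced_test = TRUE, seed = 9)
  plan <- plan_folds(ids, cfg, labels = labels)
  validate_fold_plan(plan, ids, require_coverage = FALSE)
  for (p in plan) {
    lab <- labels[match(p$test_ids, ids)]
    expect_equal(as.vector(table(lab)), c(20, 20))
  }
  all_test <- unlist(lapply(plan, `[[`, "test_ids"))
  expect_false(anyDuplicated(all_test) > 0)
})

test_that("the early-stopping rule walks a loss history correctly", {
  # flat after epoch 3: best stays at 3, stop fires at 3 + patience
  flat <- c(1.0, 0.8, 0.5, rep(0.5, 60))
  r <- early_stop_epoch(flat, patience = 50)
  expect_equal(r$stop_epoch, 53)
  expect_equal(r$best_epoch, 3)
  # strictly decreasing: never stops
  r2 <- early_stop_epoch(seq(1, 0.01, length.out = 100), patience = 50)
  expect_true(is.na(r2$stop_epoch))
  expect_equal(r2$best_epoch, 100)
  # tie on equal losses: earliest epoch wins
  r3 <- early_stop_epoch(c(0.5, 0.5, 0.5), patience = 10)
  expect_equal(r3$best_epoch, 1)
})

test_that("training reduces loss on separable data and is seed-deterministic", {
  ds <- tiny_dataset(n_per_class = 12, image_size = 36)
  cfg <- protocol_config(n_folds = 2, val_size = 4, sizes = c(8),
                         max_epochs = 8, early_stop_patience = 10,
                         batch_size = 8, seed = 1)
  tr <- ds[c(1:8, 13:20)]; vl <- ds[c(9:10, 21:22)]
  m1 <- train_model(build_network(36, 36, 3, 2, n_conv_pairs = 3), tr, vl,
                    cfg, seed = 4)
  expect_lt(min(m1$history$train_loss), m1$history$train_loss[1])
  expect_equal(nrow(m1$history), 8)
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))
  m2 <- train_model(build_network(36, 36, 3, 2, n_conv_pairs = 3), tr, vl,
                    cfg, seed = 4)
  expect_identical(m1$weights, m2$weights)
  expect_error(train_model(build_network(36, 36, 3, 2, n_conv_pairs = 3),
                           tr, tr[1], cfg), "overlap")
})

test_that("the learning-curve driver records folds x sizes with fixed test sets", {
  ds <- tiny_dataset(n_per_class = 30, image_size = 36)
  cfg <- protocol_config(n_folds = 2, val_size = 10, sizes = c(5, 10),
                         max_epochs = 2, early_stop_patience = 5,
                         positive_class = "blast", seed = 21)
  res <- run_learning_curve(ds, cfg)
  expect_equal(nrow(res), 4)  # 2 folds x 2 sizes
  expect_equal(sort(unique(res$train_size)), c(5, 10))
  expect_true(all(res$metric_value >= 0 & res$metric_value <= 1))
  plan <- attr(res, "plan")
  # identical test set across sizes within a fold is plan-structural
  expect_length(plan[[1]]$test_ids, 30)
  # end-to-end determinism
  res2 <- run_learning_curve(ds, cfg)
  expect_equal(res$metric_value, res2$metric_value)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_learning_curve(res, path)
  back <- read_learning_curve(path)
  expect_equal(back$metric_value, res$metric_value)
  expect_equal(names(back), c("fold", "train_size", "metric_name",
                              "metric_value", "epochs_trained", "seed"))
})
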
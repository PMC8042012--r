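#' Protocol configuration
#'
#' Houses every constant of the nested incremental cross-validation design:
#' tenfold cross-validation with pairwise-disjoint test sets covering the
#' whole dataset, a fixed 25-image validation set per fold, and nested
#' training subsets growing from 10 to 200 images in steps of 10, each model
#' trained from scratch with early stopping (patience 50). Multiclass runs
#' additionally balance the training set to 150 images per class by
#' augmentation. All of these are overridable.
#'
#' @param n_folds number of cross-validation folds.
#' @param test_size images per fold's test set; `NULL` uses `n / n_folds`.
#' @param val_size images in the per-fold validation set.
#' @param sizes increasing vector of nested training-set sizes.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param max_epochs hard cap on epochs.
#' @param learning_rate,batch_size Adam settings.
#' @param augment per-epoch random augmentation on/off.
#' @param augment_mode `"replace"` (each training image augmented once per
#'   epoch) or `"append"` (a random number of augmented copies is added to
#'   the untouched originals each epoch).
#' @param balance_target per-class training-set size for multiclass runs.
#' @param metric `"roc_auc"` (binary) or `"f1_macro"` (multiclass).
#' @param positive_class label treated as positive for ROC; `NULL` takes the
#'   first factor level.
#' @param balanced_test draw each test set balanced across classes (the
#'   large-dataset variant; disjointness across folds is then enforced on
#'   the test side only).
#' @param n_conv_pairs conv/pool pairs for the network; `NULL` picks the
#'   largest feasible for the image size (capped at 6).
#' @param background_color fill color for rotation augmentation; `NULL`
#'   estimates it from each image border.
#' @param seed master seed for the whole protocol.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(n_folds = 10L, test_size = NULL, val_size = 25L,
                            sizes = seq(10L, 200L, by = 10L),
                            early_stop_patience = 50L, max_epochs = 500L,
                            learning_rate = 1e-3, batch_size = 16L,
                            augment = TRUE,
                            augment_mode = c("replace", "append"),
                            balance_target = 150L,
                            metric = c("roc_auc", "f1_macro"),
                            positive_class = NULL, balanced_test = FALSE,
                            n_conv_pairs = NULL, background_color = NULL,
                            seed = 1L) {
  stopifnot(n_folds >= 2, val_size >= 1, length(sizes) >= 1,
            all(diff(sizes) > 0), early_stop_patience >= 1, max_epochs >= 1)
  structure(list(n_folds = as.integer(n_folds), test_size = test_size,
                 val_size = as.integer(val_size), sizes = as.integer(sizes),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 augment = augment, augment_mode = match.arg(augment_mode),
                 balance_target = as.integer(balance_target),
                 metric = match.arg(metric), positive_class = positive_class,
                 balanced_test = balanced_test,
                 n_conv_pairs = n_conv_pairs,
                 background_color = background_color,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Plan nested incremental cross-validation folds
#'
#' Splits the sample ids into `n_folds` pairwise-disjoint test sets whose
#' union is the whole dataset (every id is tested exactly once). Within each
#' fold the remaining ids are split into a fixed validation set and a
#' training pool; the pool is shuffled once and nested training subsets are
#' its growing prefixes, so each subset contains the previous one.
#'
#' With `balanced_test = TRUE` (large-dataset variant) each test set is drawn
#' balanced across classes from the ids not yet tested; coverage of all ids
#' is then not required, only test-set disjointness across folds.
#'
#' @param sample_ids character vector of unique ids.
#' @param config a [protocol_config()].
#' @param seed seed for the plan; defaults to the config's.
#' @param labels factor parallel to `sample_ids`; required for
#'   `balanced_test`.
#' @return a `fold_plan`: list of folds, each with `test_ids`, `val_ids`,
#'   `pool_ids` and `subsets` (named list of nested id vectors).
#' @export
plan_folds <- function(sample_ids, config, seed = config$seed,
                       labels = NULL) {
  n <- length(sample_ids)
  stopifnot(!anyDuplicated(sample_ids))
  k <- config$n_folds
  test_size <- config$test_size %||% (n %/% k)
  if (config$balanced_test && is.null(labels))
    stop("balanced_test requires labels")
  folds <- with_seed(seed, {
    if (config$balanced_test) {
      classes <- levels(labels)
      per_class <- test_size %/% length(classes)
      remaining <- rep(TRUE, n)
      lapply(seq_len(k), function(f) {
        test_idx <- unlist(lapply(classes, function(cl) {
          cand <- which(remaining & labels == cl)
          if (length(cand) < per_class)
            stop("configuration error: not enough untested '", cl,
                 "' images for a balanced test set in fold ", f)
          sample(cand, per_class)
        }))
        remaining[test_idx] <<- FALSE
        rest <- setdiff(seq_len(n), test_idx)
        val_idx <- sample(rest, config$val_size)
        pool <- sample(setdiff(rest, val_idx))
        list(test = test_idx, val = val_idx, pool = pool)
      })
    } else {
      perm <- sample(n)
      sizes_per_fold <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
      stops <- cumsum(sizes_per_fold)
      starts <- c(1, head(stops, -1) + 1)
      lapply(seq_len(k), function(f) {
        test_idx <- perm[starts[f]:stops[f]]
        rest <- setdiff(seq_len(n), test_idx)
        if (length(rest) < config$val_size + max(config$sizes))
          stop("configuration error: ", length(rest), " non-test samples ",
               "cannot provide ", config$val_size, " validation + ",
               max(config$sizes), " training images")
        val_idx <- sample(rest, config$val_size)
        pool <- sample(setdiff(rest, val_idx))
        list(test = test_idx, val = val_idx, pool = pool)
      })
    }
  })
  plan <- lapply(folds, function(f) {
    subsets <- lapply(config$sizes, function(s) sample_ids[f$pool[seq_len(s)]])
    names(subsets) <- config$sizes
    list(test_ids = sample_ids[f$test], val_ids = sample_ids[f$val],
         pool_ids = sample_ids[f$pool], subsets = subsets)
  })
  structure(plan, class = "fold_plan", seed = seed)
}

#' Check every structural invariant of a fold plan
#'
#' Asserts pairwise disjointness of test sets, per-fold disjointness of
#' test/validation/pool, strict nesting of the training subsets, and (unless
#' the plan was balanced-test) that the test sets cover all ids.
#'
#' @param plan a `fold_plan`.
#' @param sample_ids the full id vector the plan was built from.
#' @param require_coverage test sets must partition `sample_ids`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_fold_plan <- function(plan, sample_ids, require_coverage = TRUE) {
  all_test <- unlist(lapply(plan, `[[`, "test_ids"))
  if (anyDuplicated(all_test))
    stop("test sets are not pairwise disjoint")
  if (require_coverage && !setequal(all_test, sample_ids))
    stop("test sets do not cover all sample ids")
  for (f in seq_along(plan)) {
    p <- plan[[f]]
    parts <- c(p$test_ids, p$val_ids, p$pool_ids)
    if (anyDuplicated(parts))
      stop("fold ", f, ": test/val/pool are not disjoint")
    if (require_coverage && !setequal(parts, sample_ids))
      stop("fold ", f, ": test/val/pool do not partition the ids")
    for (j in seq_along(p$subsets)[-1]) {
      if (!all(p$subsets[[j - 1]] %in% p$subsets[[j]]))
        stop("fold ", f, ": training subsets are not nested at step ", j)
    }
  }
  invisible(TRUE)
}

# Evaluate one trained model on a test set under the configured metric.
.eval_metric <- function(model, test_set, config) {
  probs <- predict_proba(model, test_set$images)
  if (config$metric == "roc_auc") {
    pos <- config$positive_class %||% levels(test_set$labels)[1]
    roc_auc(probs[, pos], test_set$labels == pos)
  } else {
    pred <- factor(model$class_order[max.col(probs, ties.method = "first")],
                   levels = levels(test_set$labels))
    f1_macro(pred, test_set$labels)
  }
}

#' Run the incremental learning-curve experiment
#'
#' For every fold and every nested training-set size, initializes a fresh
#' network, trains it with augmentation and early stopping, and scores it on
#' the fold's fixed test set (identical across sizes within a fold). For
#' multiclass metrics the training subset is first balanced to
#' `config$balance_target` images per class by augmentation.
#'
#' @param dataset a `labeled_dataset`.
#' @param config a [protocol_config()].
#' @param spec optional `network_spec`; by default built for the dataset's
#'   image size with [max_conv_pairs()] pairs (capped at 6).
#' @param keep_models keep every trained model (for downstream
#'   interpretability analyses); stored in the `models` attribute as
#'   `models[[fold]][[as.character(size)]]`.
#' @param verbose print one line per trained model.
#' @return a `learning_curve_result` tibble with columns `fold`,
#'   `train_size`, `metric_name`, `metric_value`, `epochs_trained`, `seed`,
#'   and attributes `plan` (the fold plan) and optionally `models`.
#' @export
run_learning_curve <- function(dataset, config, spec = NULL,
                               keep_models = FALSE, verbose = FALSE) {
  d <- dim(dataset$images)
  if (is.null(spec)) {
    pairs <- config$n_conv_pairs %||% max_conv_pairs(d[1], d[2])
    spec <- build_network(d[1], d[2], d[3], nlevels(dataset$labels),
                          n_conv_pairs = pairs)
  }
  plan <- plan_folds(dataset$sample_id, config, labels = dataset$labels)
  validate_fold_plan(plan, dataset$sample_id,
                     require_coverage = !config$balanced_test)
  rows <- list()
  models <- if (keep_models) vector("list", length(plan)) else NULL
  for (f in seq_along(plan)) {
    p <- plan[[f]]
    test_set <- dataset[p$test_ids]
    val_set <- dataset[p$val_ids]
    if (keep_models) models[[f]] <- list()
    for (s in config$sizes) {
      train_set <- dataset[p$subsets[[as.character(s)]]]
      if (config$metric == "f1_macro") {
        seed_bal <- derive_seed(config$seed, f, s, 3L)
        train_set <- with_seed(seed_bal,
          balance_by_augmentation(train_set, config$balance_target,
                                  fill = config$background_color))
      }
      seed_fs <- derive_seed(config$seed, f, s)
      model <- train_model(spec, train_set, val_set, config, seed = seed_fs)
      value <- .eval_metric(model, test_set, config)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fold = f, train_size = s, metric_name = config$metric,
        metric_value = value,
        epochs_trained = nrow(model$history), seed = seed_fs)
      if (keep_models) models[[f]][[as.character(s)]] <- model
      if (verbose)
        message(sprintf("fold %d size %3d: %s = %.3f (%d epochs)",
                        f, s, config$metric, value, nrow(model$history)))
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("learning_curve_result", class(res))
  attr(res, "plan") <- plan
  if (keep_models) attr(res, "models") <- models
  res
}

#' Write / read a learning-curve result as CSV
#'
#' @param result a `learning_curve_result`.
#' @param path CSV path (header
#'   `fold,train_size,metric_name,metric_value,epochs_trained,seed`).
#' @return `path` invisibly; `read_learning_curve` returns the tibble.
#' @export
write_learning_curve <- function(result, path) {
  write.csv(as.data.frame(result)[, c("fold", "train_size", "metric_name",
                                      "metric_value", "epochs_trained",
                                      "seed")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_learning_curve
#' @export
read_learning_curve <- function(path) {
  res <- tibble::as_tibble(read.csv(path))
  class(res) <- c("learning_curve_result", class(res))
  res
}
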
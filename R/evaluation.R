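#' Empirical ROC curve
#'
#' Sweeps the classification threshold over all observed scores (descending,
#' preceded by `Inf`) and records the false- and true-positive rates; the
#' area under the curve is the trapezoidal area, identical to the
#' probability that a random positive outscores a random negative with ties
#' counting one half.
#'
#' @param scores numeric positive-class scores.
#' @param labels logical (or coercible) positive-class indicators; both
#'   classes must be present.
#' @return a `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined metric: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last]; fp <- cumsum(!l)[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc), class = "roc_curve")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive receives a higher score than a randomly chosen negative,
#' ties counting 1/2. Equals the trapezoidal area under [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined metric: both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Vertically averaged ROC curve across folds
#'
#' Interpolates each fold's TPR linearly onto a common FPR grid and averages.
#' Reports both the AUC of the mean curve and the mean of the per-fold AUCs
#' (the two need not coincide).
#'
#' @param curves list of [roc_curve()] objects.
#' @param grid_size number of FPR grid points.
#' @return a `roc_curve` on the grid with extra fields `mean_auc`
#'   (mean of per-fold AUCs) and `sd_auc`.
#' @export
mean_roc <- function(curves, grid_size = 101L) {
  stopifnot(length(curves) >= 1)
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(curves, function(cv) {
    approx(cv$fpr, cv$tpr, xout = grid, method = "linear",
           ties = list("ordered", max), rule = 2)$y
  }, numeric(grid_size))
  tpr <- rowMeans(tprs)
  aucs <- vapply(curves, `[[`, numeric(1), "auc")
  structure(list(thresholds = rep(NA_real_, grid_size), fpr = grid,
                 tpr = tpr,
                 auc = sum(diff(grid) * (head(tpr, -1) + tpr[-1]) / 2),
                 mean_auc = mean(aucs), sd_auc = sd(aucs)),
            class = "roc_curve")
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over the truth's classes of `2PR / (P + R)`, with a
#' class's F1 defined as 0 when precision + recall is 0. Chosen over
#' micro-averaging because the test sets are class-imbalanced.
#'
#' @param pred,truth factors (or coercible) of equal length.
#' @return F1 in `[0, 1]`.
#' @export
f1_macro <- function(pred, truth) {
  if (length(truth) == 0) stop("empty input")
  stopifnot(length(pred) == length(truth))
  truth <- as.factor(truth)
  pred <- factor(pred, levels = union(levels(truth), unique(as.character(pred))))
  f1 <- vapply(levels(truth)[table(truth) > 0], function(cl) {
    tp <- sum(pred == cl & truth == cl)
    prec_den <- sum(pred == cl); rec_den <- sum(truth == cl)
    p <- if (prec_den > 0) tp / prec_den else 0
    r <- tp / rec_den
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Confusion matrix with row percentages
#'
#' @param pred,truth label vectors drawn from `class_order`.
#' @param class_order ordered class labels.
#' @return a `confusion_matrix`: list with `counts` (rows = true class),
#'   `row_percent` (rows sum to 100; `NA` for classes absent from the
#'   truth), and `per_class_n` (row sums).
#' @export
confusion <- function(pred, truth, class_order = levels(as.factor(truth))) {
  unknown <- setdiff(unique(c(as.character(pred), as.character(truth))),
                     class_order)
  if (length(unknown))
    stop("unknown label: '", unknown[1], "'")
  pred <- factor(pred, levels = class_order)
  truth <- factor(truth, levels = class_order)
  counts <- unclass(table(truth = truth, pred = pred))
  n <- rowSums(counts)
  pct <- counts / n * 100
  pct[n == 0, ] <- NA_real_
  structure(list(counts = counts, row_percent = pct, per_class_n = n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (row %, n per true class on the right):\n")
  m <- cbind(round(x$row_percent, 1), n = x$per_class_n)
  print(m)
  invisible(x)
}

#' Box-summary of learning-curve values per training-set size
#'
#' Quartiles use linear interpolation of order statistics; whiskers extend to
#' the most extreme data points within 1.5 interquartile ranges of the box,
#' and points beyond the whiskers are listed as outliers.
#'
#' @param values numeric vector (e.g. per-fold metric values).
#' @param train_size optional grouping vector; when given, one summary row
#'   per unique size is returned.
#' @return a tibble with `train_size` (if grouped), `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, and a list-column `outliers`.
#' @export
summarize_box <- function(values, train_size = NULL) {
  one <- function(v, size = NA) {
    stopifnot(length(v) >= 1)
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    tibble::tibble(train_size = size, median = q[2], q1 = q[1], q3 = q[3],
                   whisker_low = min(inside), whisker_high = max(inside),
                   outliers = list(sort(v[v < lo_fence | v > hi_fence])))
  }
  if (is.null(train_size)) return(one(values)[-1])
  stopifnot(length(values) == length(train_size))
  do.call(rbind, lapply(sort(unique(train_size)), function(s)
    one(values[train_size == s], s)))
}
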
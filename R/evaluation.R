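# Assessment machinery: macro-averaged multi-class metrics, regression
# metrics, repeated stratified k-fold CV, LOOCV, and leave-one-feature-out
# ablation.

#' Per-class confusion counts
#'
#' One-vs-rest TP/TN/FP/FN for every class, from parallel vectors of true
#' and predicted labels. For each class these four counts sum to n.
#'
#' @param truth,pred Factors (or coercible) of equal length; `pred` levels
#'   are aligned to `truth` levels.
#' @return Object of class `confusion_counts`: a data.frame with one row per
#'   class and columns `TP`, `TN`, `FP`, `FN`, plus attribute `n`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  if (length(truth) != length(pred)) {
    stop("invalid input: truth and pred lengths differ", call. = FALSE)
  }
  n <- length(truth)
  if (n < 1L) stop("invalid input: empty labels", call. = FALSE)
  rows <- lapply(levels(truth), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    data.frame(class = cl, TP = tp, TN = n - tp - fn - fp, FP = fp, FN = fn)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  class(out) <- c("confusion_counts", class(out))
  out
}

ratio0 <- function(num, den) if (den == 0) 0 else num / den

#' Macro-averaged multi-class classification metrics
#'
#' Average accuracy `mean_i (TP_i + TN_i)/n`, error rate (its complement),
#' macro precision and recall (per-class means), macro F1 (harmonic mean of
#' macro precision and recall), and macro MCC (mean of per-class one-vs-rest
#' binary MCCs). Per-class ratios with a zero denominator contribute 0,
#' which only matters for degenerate folds.
#'
#' @param counts A [confusion_counts()] table.
#' @return Named numeric vector: `average_accuracy`, `error_rate`,
#'   `precision`, `recall`, `F1`, `MCC`.
#' @export
macro_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts") || nrow(counts) == 0L) {
    stop("invalid input: expected non-empty confusion counts", call. = FALSE)
  }
  n <- attr(counts, "n")
  acc <- mean((counts$TP + counts$TN) / n)
  prec <- mean(mapply(ratio0, counts$TP, counts$TP + counts$FP))
  rec <- mean(mapply(ratio0, counts$TP, counts$TP + counts$FN))
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  mcc <- mean(mapply(function(tp, tn, fp, fn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }, counts$TP, counts$TN, counts$FP, counts$FN))
  c(average_accuracy = acc, error_rate = 1 - acc, precision = prec,
    recall = rec, F1 = f1, MCC = mcc)
}

#' Regression metrics: PCC, MAE, RMSE
#'
#' Pearson correlation coefficient, mean absolute error and root mean
#' squared error between predicted and actual values. PCC requires at least
#' two instances and non-constant inputs.
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return Named numeric vector `PCC`, `MAE`, `RMSE` (MAE/RMSE in the units
#'   of the targets, here mg/l).
#' @export
regression_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("invalid input: predicted and actual lengths differ", call. = FALSE)
  }
  if (length(actual) < 2L) {
    stop("invalid input: need at least 2 instances", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    stop("variance error: PCC undefined for constant input", call. = FALSE)
  }
  err <- predicted - actual
  c(PCC = stats::cor(predicted, actual),
    MAE = mean(abs(err)),
    RMSE = sqrt(mean(err^2)))
}

#' Repeated stratified k-fold cross validation
#'
#' Partitions the data into k class-stratified folds, holds each fold out
#' once per repeat, pools the held-out predictions within a repeat, and
#' reports the mean and standard deviation of every metric over the
#' repeats. Classification (factor `y`) yields macro metrics; regression
#' (numeric `y`) yields PCC/MAE/RMSE.
#'
#' @param x Feature matrix.
#' @param y Targets (factor for classification, numeric for regression).
#' @param train_fn `function(x, y)` returning a fitted model.
#' @param predict_fn `function(model, x)` returning labels or numbers.
#' @param k Folds per repeat (default 10).
#' @param repeats Number of independent randomizations (default 10).
#' @param seed Integer seed; repeat r uses `seed + r - 1` for its folds.
#' @return List with `per_repeat` (repeats x metrics matrix), `mean`, `sd`.
#' @export
repeated_kfold_cv <- function(x, y, train_fn, predict_fn,
                              k = 10L, repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  n <- length(y)
  if (n < k) stop("fold error: fewer instances than folds", call. = FALSE)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- factor(y)
  per_rep <- NULL
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, k, seed + r - 1L)
    pred <- if (classification) character(n) else numeric(n)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      m <- train_fn(x[tr, , drop = FALSE], y[tr])
      p <- predict_fn(m, x[te, , drop = FALSE])
      pred[te] <- if (classification) as.character(p) else p
    }
    met <- if (classification) {
      macro_metrics(confusion_counts(y, factor(pred, levels = levels(y))))
    } else {
      regression_metrics(pred, y)
    }
    per_rep <- rbind(per_rep, met)
  }
  rownames(per_rep) <- paste0("repeat", seq_len(repeats))
  list(per_repeat = per_rep,
       mean = colMeans(per_rep),
       sd = apply(per_rep, 2L, stats::sd))
}

#' Leave-one-out cross validation
#'
#' n train/test cycles, each holding out one instance; metrics are computed
#' from the n held-out predictions.
#'
#' @inheritParams repeated_kfold_cv
#' @return List with `predictions` (length n, aligned to the input) and
#'   `metrics`.
#' @export
loocv <- function(x, y, train_fn, predict_fn) {
  x <- as.matrix(x)
  n <- length(y)
  if (n < 3L) stop("insufficient data: LOOCV needs n >= 3", call. = FALSE)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- factor(y)
  pred <- if (classification) character(n) else numeric(n)
  for (i in seq_len(n)) {
    m <- train_fn(x[-i, , drop = FALSE], y[-i])
    p <- predict_fn(m, x[i, , drop = FALSE])
    pred[i] <- if (classification) as.character(p) else p
  }
  metrics <- if (classification) {
    macro_metrics(confusion_counts(y, factor(pred, levels = levels(y))))
  } else {
    regression_metrics(pred, y)
  }
  list(predictions = pred, metrics = metrics)
}

#' Leave-one-feature-out ablation
#'
#' For each feature in a selected subset, re-evaluates the model with that
#' feature removed and reports the percentage change of every metric
#' relative to the full-subset baseline:
#' `100 * (metric_without - metric_with_all) / metric_with_all`.
#' `eval_fn` should embody the complete evaluation protocol, including any
#' hyperparameter retuning, so the ablated models are tuned the same way
#' the baseline was.
#'
#' @param x Feature matrix whose columns are the subset under study
#'   (at least 2 columns).
#' @param y Targets.
#' @param eval_fn `function(x, y)` returning a named numeric vector of
#'   metrics.
#' @return List with `baseline` (metrics of the full subset) and `changes`,
#'   a data.frame of percentage changes, one row per removed feature, sorted
#'   by descending mean absolute change.
#' @export
ablation <- function(x, y, eval_fn) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    stop("invalid argument: ablation needs at least 2 features", call. = FALSE)
  }
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(x)))
  baseline <- eval_fn(x, y)
  changes <- vapply(seq_len(ncol(x)), function(j) {
    m <- eval_fn(x[, -j, drop = FALSE], y)
    100 * (m - baseline) / ifelse(baseline == 0, NA_real_, baseline)
  }, baseline)
  changes <- if (is.null(dim(changes))) {
    matrix(changes, ncol = 1L, dimnames = list(NULL, names(baseline)))
  } else {
    t(changes)
  }
  rownames(changes) <- feats
  ord <- order(-rowMeans(abs(changes), na.rm = TRUE))
  out <- as.data.frame(changes[ord, , drop = FALSE])
  out <- cbind(feature_removed = feats[ord], out)
  rownames(out) <- NULL
  list(baseline = baseline, changes = out)
}
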
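# The two-stage predictor: a multi-class SVC assigns the expression class
# (high / medium / low soluble yield), then the epsilon-SVR trained on that
# class's instances alone predicts the real-valued yield in mg/l.

#' Expression class labels
#'
#' In alphabetical order, which is also the probability-triple order used in
#' prediction output: (High, Low, Medium).
#' @export
CLASS_LEVELS <- c("high", "low", "medium")

#' Map soluble yield to expression class
#'
#' Thresholds with inclusive boundaries: low for yield <= 0.5 mg/l, high for
#' yield >= 100 mg/l, medium in between.
#'
#' @param yield Positive numeric vector of yields in mg/l.
#' @return Factor with levels `high`, `low`, `medium`.
#' @examples
#' yield_to_class(c(0.5, 50, 100))
#' @export
yield_to_class <- function(yield) {
  if (!is.numeric(yield) || any(!is.finite(yield)) || any(yield <= 0)) {
    stop("invalid input: yields must be positive finite mg/l values",
         call. = FALSE)
  }
  factor(ifelse(yield <= 0.5, "low", ifelse(yield >= 100, "high", "medium")),
         levels = CLASS_LEVELS)
}

# Closed/open class intervals on the mg/l scale used for clamping stage-2
# output into the predicted class. `floor` and `cap` bound the open ends.
class_interval <- function(label, floor, cap) {
  eps <- 1e-6
  switch(label,
         low = c(floor, 0.5),
         medium = c(0.5 + eps, 100 - eps),
         high = c(100, cap))
}

# Fit the feature subset + standardizer + machine for one task.
fit_task <- function(xfull, target, task, subsets, config, regression) {
  std_all <- fit_standardizer(xfull)
  if (config$feature_selection == "paper") {
    sel <- unname(subsets[[task]])
  } else {
    zs <- apply_standardizer(std_all, xfull)
    colnames(zs) <- colnames(xfull)
    idx <- forward_select(zs, target,
                          max_subset_size = config$max_subset_size,
                          tie_tol = config$tie_tol)
    sel <- colnames(xfull)[idx]
  }
  std <- fit_standardizer(xfull[, sel, drop = FALSE])
  z <- apply_standardizer(std, xfull[, sel, drop = FALSE])
  if (regression) {
    gs <- grid_search(z, target, config$svr_grid,
                      cv_folds = min(config$cv_folds, length(target)),
                      seed = config$seed)
    fit <- svr_train(z, target, gs$best$C, gs$best$gamma, gs$best$epsilon)
  } else {
    gs <- grid_search(z, target, config$svc_grid,
                      cv_folds = config$cv_folds, seed = config$seed)
    fit <- svc_train(z, target, gs$best$C, gs$best$gamma)
  }
  list(features = sel, standardizer = std, fit = fit, grid_best = gs$best)
}

#' Train the two-stage predictor
#'
#' Stage 1: a multi-class SVC trained on all instances, labelled by
#' [yield_to_class()]. Stage 2: three epsilon-SVR models, each trained only
#' on the instances of its own class, on raw mg/l (or log10 mg/l when
#' `config$log_scale_regression` is TRUE). Every task gets its own feature
#' subset (CFS forward selection on the standardized training features, or
#' the published subsets) and its own standardizer, fitted on that task's
#' training rows only and frozen into the model.
#'
#' @param dataset A [labelled_dataset()] of sequences and yields, with at
#'   least 2 instances per class.
#' @param config A [default_config()] list.
#' @param registry A [feature_registry()].
#' @param suite A property suite, see [default_property_suite()].
#' @return Object of class `TwoStageModel`.
#' @export
train_two_stage <- function(dataset, config = default_config(),
                            registry = feature_registry(),
                            suite = default_property_suite()) {
  stopifnot(inherits(dataset, "LabelledDataset"))
  classes <- yield_to_class(dataset$yield)
  missing <- CLASS_LEVELS[table(classes)[CLASS_LEVELS] < 2L]
  if (length(missing) > 0L) {
    stop(sprintf("uncovered class: need >= 2 instances of class '%s'",
                 missing[1L]), call. = FALSE)
  }
  xfull <- feature_matrix(dataset$records, registry, suite)
  subsets <- paper_feature_subsets(registry, config$tyrosine_tm_variant)

  classifier <- fit_task(xfull, classes, "classification", subsets, config,
                         regression = FALSE)
  regressors <- lapply(CLASS_LEVELS, function(cl) {
    rows <- classes == cl
    y <- dataset$yield[rows]
    if (config$log_scale_regression) y <- log10(y)
    fit_task(xfull[rows, , drop = FALSE], y,
             paste0("reg_", cl), subsets, config, regression = TRUE)
  })
  names(regressors) <- CLASS_LEVELS

  structure(list(classifier = classifier,
                 regressors = regressors,
                 config = config,
                 registry = registry,
                 n_train = length(dataset$yield),
                 class_counts = table(classes)),
            class = "TwoStageModel")
}

#' @export
print.TwoStageModel <- function(x, ...) {
  cat(sprintf("TwoStageModel trained on %d instances (%s)\n", x$n_train,
              paste(names(x$class_counts), as.vector(x$class_counts),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  stage-1 features: %s\n",
              paste(x$classifier$features, collapse = ", ")))
  invisible(x)
}

#' Predict expression class and yield for sequences
#'
#' Stage 1 assigns each sequence a class label (the argmax of the coupled
#' probability triple, ordered High, Low, Medium); stage 2 applies the
#' regressor of the assigned class — misclassifications are not corrected
#' downstream — and the predicted yield is clamped into the predicted
#' class's interval (low: (0, 0.5], medium: (0.5, 100), high: [100, cap]).
#'
#' @param model A [train_two_stage()] model.
#' @param seqs A `SequenceRecord`, a list of them, or a character vector of
#'   sequences.
#' @param registry,suite Must match training; defaults as in training.
#' @return data.frame with columns `id`, `class`, `p_high`, `p_low`,
#'   `p_medium`, `yield_mg_per_l`.
#' @export
predict_two_stage <- function(model, seqs,
                              registry = model$registry,
                              suite = default_property_suite()) {
  if (!inherits(model, "TwoStageModel")) {
    stop("model-state error: not a trained TwoStageModel", call. = FALSE)
  }
  if (inherits(seqs, "SequenceRecord")) seqs <- list(seqs)
  if (is.character(seqs)) {
    seqs <- lapply(seq_along(seqs), function(i) {
      sequence_record(paste0("seq", i), seqs[i])
    })
  }
  xfull <- feature_matrix(seqs, registry, suite)
  clf <- model$classifier
  z <- apply_standardizer(clf$standardizer,
                          xfull[, clf$features, drop = FALSE])
  cls <- svc_predict(clf$fit, z)
  yields <- vapply(seq_along(seqs), function(i) {
    lab <- as.character(cls$label[i])
    reg <- model$regressors[[lab]]
    zi <- apply_standardizer(reg$standardizer,
                             xfull[i, reg$features, drop = FALSE])
    yhat <- svr_predict(reg$fit, zi)
    if (model$config$log_scale_regression) yhat <- 10^yhat
    iv <- class_interval(lab, model$config$yield_floor, model$config$high_cap)
    min(max(yhat, iv[1L]), iv[2L])
  }, numeric(1))
  data.frame(id = vapply(seqs, function(s) s$id, character(1)),
             class = as.character(cls$label),
             p_high = cls$prob[, "high"],
             p_low = cls$prob[, "low"],
             p_medium = cls$prob[, "medium"],
             yield_mg_per_l = yields,
             stringsAsFactors = FALSE)
}
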
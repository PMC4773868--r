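test_that("yield_to_class applies inclusive thresholds", {
  expect_equal(as.character(yield_to_class(c(0.5, 100, 50, 0.01, 5000))),
               c("low", "high", "medium", "low", "high"))
  expect_error(yield_to_class(c(1, 0)), "positive")
  expect_error(yield_to_class(-2), "positive")
})

# One trained model shared by the contract tests below (QD-count yield law,
# published subsets, reduced grids).
qd_model <- local({
  ds <- qd_law_dataset(n = 60, seed = 42)
  train_two_stage(ds, small_config(feature_selection = "paper", seed = 1))
})
qd_ds <- qd_law_dataset(n = 60, seed = 42)

test_that("training bookkeeping: per-class regressors and error paths", {
  cls <- yield_to_class(qd_ds$yield)
  expect_named(qd_model$regressors, CLASS_LEVELS)
  expect_equal(as.vector(qd_model$class_counts), as.vector(table(cls)))
  # each regressor was fitted on its own class rows only: the support
  # vectors can never outnumber them
  for (cl in CLASS_LEVELS) {
    expect_lte(nrow(qd_model$regressors[[cl]]$fit$sv), sum(cls == cl))
  }
  # missing class
  med <- yield_to_class(qd_ds$yield) == "medium"
  ds_med <- labelled_dataset(qd_ds$records[med], qd_ds$yield[med])
  expect_error(train_two_stage(ds_med, small_config()), "uncovered class")
  expect_error(predict_two_stage(list(), qd_ds$records[1]), "model-state")
})

test_that("the trained model recovers the planted QD law on training data", {
  pred <- predict_two_stage(qd_model, qd_ds$records)
  truth <- yield_to_class(qd_ds$yield)
  mm <- macro_metrics(confusion_counts(
    truth, factor(pred$class, levels = CLASS_LEVELS)))
  expect_gt(mm[["average_accuracy"]], 1 / 3)
  # a two-QD-dipeptide sequence built like the training data lands in the
  # medium band (yield law: 10 * QD + 0.2)
  two_qd <- withr::with_seed(77, {
    backbone <- paste(sample(setdiff(AA_ALPHABET, c("Q", "D")), 40,
                             replace = TRUE), collapse = "")
    sequence_record("probe", paste0(substr(backbone, 1, 20), "QDGG",
                                    substr(backbone, 21, 40), "QDGG"))
  })
  p <- predict_two_stage(qd_model, two_qd)
  expect_gt(p$yield_mg_per_l, 0.5)
  expect_lt(p$yield_mg_per_l, 100)
})

test_that("prediction contracts: probabilities, argmax, clamping", {
  pred <- predict_two_stage(qd_model, qd_ds$records)
  probs <- as.matrix(pred[, c("p_high", "p_low", "p_medium")])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pred)), tolerance = 1e-9)
  expect_equal(pred$class,
               CLASS_LEVELS[max.col(probs, ties.method = "first")])
  expect_true(all(pred$yield_mg_per_l > 0))
  iv <- list(low = c(0, 0.5), medium = c(0.5, 100), high = c(100, Inf))
  for (i in seq_len(nrow(pred))) {
    band <- iv[[pred$class[i]]]
    expect_gte(pred$yield_mg_per_l[i], band[1])
    expect_lte(pred$yield_mg_per_l[i], band[2])
  }
})

test_that("stage-2 routing: swapping one regressor only moves its class", {
  pred <- predict_two_stage(qd_model, qd_ds$records)
  tweaked <- qd_model
  tweaked$regressors$medium$fit$b <- tweaked$regressors$medium$fit$b + 5
  pred2 <- predict_two_stage(tweaked, qd_ds$records)
  moved <- pred$yield_mg_per_l != pred2$yield_mg_per_l
  expect_true(all(pred$class[moved] == "medium"))
  expect_identical(pred$class, pred2$class)
  # unrouted classes are bit-identical
  other <- pred$class != "medium"
  expect_identical(pred$yield_mg_per_l[other], pred2$yield_mg_per_l[other])
})

test_that("training is deterministic given data and seed", {
  ds <- qd_law_dataset(n = 60, seed = 42)
  m2 <- train_two_stage(ds, small_config(feature_selection = "paper", seed = 1))
  p1 <- predict_two_stage(qd_model, ds$records[1:5])
  p2 <- predict_two_stage(m2, ds$records[1:5])
  expect_identical(p1, p2)
})

test_that("model bundles round-trip through save/load", {
  path <- withr::local_tempfile(fileext = ".json")
  save_model(qd_model, path)
  loaded <- load_model(path)
  probes <- qd_ds$records[seq(1, 60, by = 6)]
  expect_identical(predict_two_stage(qd_model, probes),
                   predict_two_stage(loaded, probes))
  # truncated bundle
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 500), bad)
  expect_error(load_model(bad), "load error")
  # newer format version
  newer <- withr::local_tempfile(fileext = ".json")
  b <- jsonlite::fromJSON(path)
  b$format_version <- 999L
  writeLines(jsonlite::toJSON(b, auto_unbox = TRUE), newer)
  expect_error(load_model(newer), "newer")
})
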
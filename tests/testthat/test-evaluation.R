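test_that("macro metrics: identity, degenerate and oracle cases", {
  truth <- factor(rep(c("high", "low", "medium"), each = 10))
  mm <- macro_metrics(confusion_counts(truth, truth))
  expect_equal(unname(mm[c("average_accuracy", "precision", "recall",
                           "F1", "MCC")]), rep(1, 5))
  expect_equal(mm[["error_rate"]], 0)

  # everything predicted as one class on balanced labels
  allmed <- factor(rep("medium", 30), levels = levels(truth))
  mm <- macro_metrics(confusion_counts(truth, allmed))
  expect_equal(mm[["recall"]], 1 / 3)
  expect_equal(mm[["average_accuracy"]], mean(c(20, 20, 10) / 30))

  # brute-force oracle over random confusion tables
  withr::with_seed(12, {
    for (i in 1:100) {
      n <- 60
      truth <- factor(sample(c("a", "b", "c"), n, replace = TRUE,
                             prob = c(0.5, 0.3, 0.2)))
      pred <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
                     levels = levels(truth))
      mm <- macro_metrics(confusion_counts(truth, pred))
      accs <- precs <- recs <- mccs <- numeric(0)
      for (cl in levels(truth)) {
        tp <- sum(truth == cl & pred == cl)
        fp <- sum(truth != cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        tn <- n - tp - fp - fn
        accs <- c(accs, (tp + tn) / n)
        precs <- c(precs, if (tp + fp == 0) 0 else tp / (tp + fp))
        recs <- c(recs, if (tp + fn == 0) 0 else tp / (tp + fn))
        den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
        mccs <- c(mccs, if (den == 0) 0 else (tp * tn - fp * fn) / den)
      }
      p <- mean(precs); r <- mean(recs)
      expect_equal(mm[["average_accuracy"]], mean(accs), tolerance = 1e-12)
      expect_equal(mm[["error_rate"]], 1 - mean(accs), tolerance = 1e-12)
      expect_equal(mm[["precision"]], p, tolerance = 1e-12)
      expect_equal(mm[["recall"]], r, tolerance = 1e-12)
      expect_equal(mm[["F1"]],
                   if (p + r == 0) 0 else 2 * p * r / (p + r),
                   tolerance = 1e-12)
      expect_equal(mm[["MCC"]], mean(mccs), tolerance = 1e-12)
    }
  })
})

test_that("regression metrics match direct formulas", {
  y <- c(1, 3, 2, 5)
  expect_equal(unname(regression_metrics(y, y)), c(1, 0, 0))
  m <- regression_metrics(y + 1, y)
  expect_equal(unname(m), c(1, 1, 1))
  expect_error(regression_metrics(rep(1, 4), y), "variance")
  expect_error(regression_metrics(1:3, 1:4), "lengths differ")

  withr::with_seed(13, {
    for (i in 1:100) {
      a <- rnorm(50); p <- rnorm(50)
      m <- regression_metrics(p, a)
      expect_equal(m[["PCC"]],
                   sum((p - mean(p)) * (a - mean(a))) /
                     sqrt(sum((p - mean(p))^2) * sum((a - mean(a))^2)),
                   tolerance = 1e-12)
      expect_equal(m[["MAE"]], mean(abs(p - a)), tolerance = 1e-12)
      expect_equal(m[["RMSE"]], sqrt(mean((p - a)^2)), tolerance = 1e-12)
      expect_gte(m[["RMSE"]], m[["MAE"]])
      # linear scaling of both vectors scales MAE/RMSE, fixes PCC
      m2 <- regression_metrics(3 * p, 3 * a)
      expect_equal(m2[["MAE"]], 3 * m[["MAE"]], tolerance = 1e-12)
      expect_equal(m2[["RMSE"]], 3 * m[["RMSE"]], tolerance = 1e-12)
      expect_equal(m2[["PCC"]], m[["PCC"]], tolerance = 1e-12)
    }
  })
})

# 1-nearest-neighbour stand-in models keep CV tests fast and deterministic.
nn_train <- function(x, y) list(x = x, y = y)
nn_predict <- function(m, x) {
  idx <- apply(x, 1, function(r) {
    which.min(colSums((t(m$x) - r)^2))
  })
  m$y[idx]
}

test_that("repeated k-fold CV tests each instance once per repeat", {
  withr::with_seed(14, {
    x <- matrix(rnorm(40 * 2), 40, 2)
    y <- factor(rep(c("a", "b"), 20))
  })
  # partition bookkeeping via the fold generator
  for (r in 1:3) {
    fold <- periyield:::make_folds(y, 5, seed = r)
    expect_equal(sort(unlist(lapply(1:5, function(f) which(fold == f)))),
                 1:40)
  }
  res <- repeated_kfold_cv(x, y, nn_train, nn_predict,
                           k = 5, repeats = 3, seed = 1)
  expect_equal(dim(res$per_repeat), c(3, 6))
  expect_true(all(is.finite(res$mean)))
  # k = n gives the LOOCV fold structure
  foldn <- periyield:::make_folds(y, length(y), seed = 1)
  expect_equal(sort(foldn), 1:40)
  expect_error(repeated_kfold_cv(x[1:3, ], y[1:3], nn_train, nn_predict,
                                 k = 10), "fold error")
})

test_that("LOOCV returns n held-out predictions, deterministically", {
  withr::with_seed(15, {
    x <- matrix(rnorm(30), 15, 2)
    y <- x[, 1] + 0.1 * rnorm(15)
  })
  tr <- function(x, y) stats::lm.fit(cbind(1, x), y)
  pr <- function(m, x) drop(cbind(1, x) %*% m$coefficients)
  r1 <- loocv(x, y, tr, pr)
  expect_length(r1$predictions, 15)
  expect_identical(r1, loocv(x, y, tr, pr))
  expect_gte(r1$metrics[["PCC"]], 0.5)
  expect_error(loocv(x[1:2, ], y[1:2], tr, pr), "insufficient data")
})

test_that("ablation reports percentage changes against the full subset", {
  # formula check with a stub evaluator
  vals <- c(full = 0.5, without_f1 = 0.4, without_f2 = 0.55)
  stub <- local({
    calls <- 0
    function(x, y) {
      calls <<- calls + 1
      c(metric = unname(vals[calls]))
    }
  })
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  res <- ablation(x, rnorm(10), stub)
  expect_equal(res$baseline[["metric"]], 0.5)
  ch <- res$changes
  expect_equal(ch$metric[ch$feature_removed == "f1"], -20, tolerance = 1e-12)
  expect_equal(ch$metric[ch$feature_removed == "f2"], 10, tolerance = 1e-12)
  # sorted by descending impact
  expect_equal(ch$feature_removed, c("f1", "f2"))
  expect_error(ablation(x[, 1, drop = FALSE], rnorm(10), stub),
               "invalid argument")

  # construction: dropping the sole signal feature collapses the metric,
  # dropping pure noise barely moves it
  withr::with_seed(16, {
    n <- 60
    sig <- rnorm(n)
    x <- cbind(signal = sig, noise = rnorm(n))
    y <- factor(ifelse(sig > 0, "pos", "neg"))
  })
  eval_fn <- function(x, y) {
    r <- loocv(x, y, function(a, b) list(x = a, y = b), nn_predict)
    r$metrics[c("average_accuracy", "MCC")]
  }
  res <- ablation(x, y, eval_fn)
  ch <- res$changes
  expect_lt(ch$MCC[ch$feature_removed == "signal"], -50)
  expect_lt(abs(ch$average_accuracy[ch$feature_removed == "noise"]), 10)
})
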
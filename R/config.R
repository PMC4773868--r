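#' Default pipeline configuration
#'
#' All tunable parameters of the training pipeline in one list:
#'
#' * `feature_selection`: `"cfs"` (correlation-based forward selection on
#'   the standardized feature matrix) or `"paper"` (the published fixed
#'   subsets from [paper_feature_subsets()]).
#' * `max_subset_size`, `tie_tol`: forward-search stopping controls.
#' * `svc_grid`, `svr_grid`: hyperparameter grids; defaults are the
#'   conventional exponential grids C in 2^(-5..15), gamma in 2^(-15..3)
#'   (step 2 in the exponent) and epsilon in {0.01, 0.1, 1}.
#' * `cv_folds`: folds used inside the grid search.
#' * `log_scale_regression`: fit the class regressors on log10(mg/l)
#'   instead of raw mg/l (default FALSE: raw class-local scale).
#' * `yield_floor`, `high_cap`: limits used when clamping predictions into
#'   the predicted class interval (mg/l); the cap sits above the largest
#'   curated yield (5,310 mg/l).
#' * `tyrosine_tm_variant`: see [paper_feature_subsets()].
#' * `seed`: master seed for grid-search folds.
#'
#' @param ... Named overrides of any default.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    feature_selection = "cfs",
    max_subset_size = 20L,
    tie_tol = 1e-6,
    svc_grid = list(C = 2^seq(-5, 15, 2), gamma = 2^seq(-15, 3, 2)),
    svr_grid = list(C = 2^seq(-5, 15, 2), gamma = 2^seq(-15, 3, 2),
                    epsilon = c(0.01, 0.1, 1)),
    cv_folds = 5L,
    log_scale_regression = FALSE,
    yield_floor = 1e-3,
    high_cap = 1e4,
    tyrosine_tm_variant = "count",
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("invalid argument: unknown config field '%s'", unknown[1L]),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}
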
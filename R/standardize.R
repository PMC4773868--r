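#' Fit a Z-score standardization model
#'
#' Per-feature sample mean and sample (n-1 denominator) standard deviation,
#' fitted on training rows only. The fitted model is frozen and replayed on
#' any later data so prediction never re-estimates moments (no leakage).
#'
#' @param x Numeric matrix, n rows (instances) by p columns (features),
#'   n >= 2.
#' @return Object of class `StandardizationModel` with fields `mean`, `sd`
#'   (both length p) and `feature_names`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("insufficient data: standardization needs at least 2 rows",
         call. = FALSE)
  }
  structure(list(mean = colMeans(x),
                 sd = apply(x, 2L, stats::sd),
                 feature_names = colnames(x)),
            class = "StandardizationModel")
}

#' Apply a fitted standardizer
#'
#' Computes `(x - mean) / sd` per feature. Constant training features
#' (sd = 0) map to 0 rather than dividing by zero.
#'
#' @param model A [fit_standardizer()] result.
#' @param x Numeric vector (one instance) or matrix (rows = instances) whose
#'   width matches the model.
#' @return Standardized vector or matrix of the same shape.
#' @export
apply_standardizer <- function(model, x) {
  stopifnot(inherits(model, "StandardizationModel"))
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop(sprintf("contract violation: %d features supplied, model has %d",
                 ncol(x), length(model$mean)), call. = FALSE)
  }
  sd <- ifelse(model$sd > 0, model$sd, 1)
  z <- sweep(sweep(x, 2L, model$mean, `-`), 2L, sd, `/`)
  z[, model$sd == 0] <- 0
  if (vec) drop(z) else z
}
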
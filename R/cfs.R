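# Correlation-based feature selection (CFS): pick subsets whose members
# correlate with the target but not with each other, grown by forward
# search over subset size.

# Pearson correlation with a zero guard for constant inputs.
safe_cor <- function(x, y) {
  out <- suppressWarnings(stats::cor(x, y))
  out[is.na(out)] <- 0
  out
}

# Candidate "class signal" columns for a categorical target: one indicator
# per class plus the integer level coding.
class_signal_matrix <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) < 2L) {
    stop("no signal: labels contain a single class", call. = FALSE)
  }
  ind <- vapply(levels(f), function(l) as.numeric(f == l),
                numeric(length(f)))
  cbind(ind, code = as.numeric(f))
}

#' Feature-target correlation for a categorical target
#'
#' The continuous CFS variant used throughout: the target is expanded into
#' one indicator column per class plus its integer coding, and the reported
#' correlation is the Pearson correlation with whichever of those class
#' signals has the largest magnitude. Constant features return 0.
#'
#' @param x Numeric feature vector.
#' @param labels Class labels (factor or character) with at least two
#'   distinct values present.
#' @return Signed correlation in [-1, 1].
#' @export
class_correlation <- function(x, labels) {
  sig <- class_signal_matrix(labels)
  r <- safe_cor(x, sig)
  r[which.max(abs(r))]
}

# Feature-target correlations for every column of X, for either a numeric
# target (plain Pearson) or a categorical one (class_correlation).
target_correlations <- function(x, y) {
  if (is.numeric(y)) {
    if (stats::sd(y) == 0) {
      stop("no signal: target is constant", call. = FALSE)
    }
    drop(safe_cor(x, y))
  } else {
    sig <- class_signal_matrix(y)
    r <- safe_cor(x, sig)
    r[cbind(seq_len(nrow(r)), max.col(abs(r), ties.method = "first"))]
  }
}

#' CFS merit of a feature subset
#'
#' `merit = (k * mean|r_cf|) / sqrt(k + k (k - 1) * mean|r_ff|)` for a
#' subset of size k, where r_cf are feature-target and r_ff feature-feature
#' correlations. For k = 1 this reduces to |r_cf|.
#'
#' @param r_cf Feature-target correlations of the subset members.
#' @param r_ff Feature-feature correlations of all unordered member pairs
#'   (length k (k - 1) / 2; ignored for k = 1).
#' @return The merit, a non-negative real.
#' @export
cfs_merit <- function(r_cf, r_ff = numeric(0)) {
  k <- length(r_cf)
  if (k == 0L) {
    stop("invalid argument: empty subset has no merit", call. = FALSE)
  }
  if (k > 1L && length(r_ff) != k * (k - 1) / 2) {
    stop(sprintf("invalid argument: expected %d pairwise correlations, got %d",
                 k * (k - 1) / 2, length(r_ff)), call. = FALSE)
  }
  mean_ff <- if (k > 1L) mean(abs(r_ff)) else 0
  (k * mean(abs(r_cf))) / sqrt(k + k * (k - 1) * mean_ff)
}

#' Forward subset-size feature selection under the CFS merit
#'
#' Greedy growth: starting from the single feature with the best merit, each
#' step adds the feature that maximizes the subset merit, stopping when no
#' addition improves the merit by more than `tie_tol` or when
#' `max_subset_size` is reached. Ties are broken toward the lowest column
#' index, so the search is deterministic.
#'
#' @param x Numeric matrix of (standardized) features, n rows by p columns.
#' @param y Target: numeric for regression tasks, factor/character class
#'   labels for classification.
#' @param max_subset_size Largest subset considered (default 20).
#' @param tie_tol Minimum merit improvement to keep growing (default 1e-6).
#' @return Integer vector of selected column indices, in selection order,
#'   with the merit trajectory as attribute `"merit"` and column names (if
#'   any) as names.
#' @export
forward_select <- function(x, y, max_subset_size = 20L, tie_tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L || p < 1L) {
    stop("invalid input: need at least 3 rows and 1 feature", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("no signal: target is constant", call. = FALSE)
  }
  r_cf <- abs(target_correlations(x, y))

  selected <- which.max(r_cf)  # which.max takes the first (lowest index) tie
  merit <- r_cf[selected]
  merits <- merit
  pair_abs_sum <- 0  # sum of |r_ff| over pairs inside the subset

  while (length(selected) < min(max_subset_size, p)) {
    k <- length(selected)
    # |r_ff| between every candidate and each subset member, vectorized
    add_ff <- colSums(abs(safe_cor(x[, selected, drop = FALSE], x)))
    cand_pair_sum <- pair_abs_sum + add_ff
    k1 <- k + 1
    mean_cf <- (sum(r_cf[selected]) + r_cf) / k1
    mean_ff <- cand_pair_sum / (k1 * (k1 - 1) / 2)
    cand_merit <- (k1 * mean_cf) / sqrt(k1 + k1 * (k1 - 1) * mean_ff)
    cand_merit[selected] <- -Inf
    best <- which.max(cand_merit)
    if (cand_merit[best] <= merit + tie_tol) break
    pair_abs_sum <- cand_pair_sum[best]
    selected <- c(selected, best)
    merit <- cand_merit[best]
    merits <- c(merits, merit)
  }
  out <- as.integer(selected)
  if (!is.null(colnames(x))) names(out) <- colnames(x)[out]
  attr(out, "merit") <- unname(merits)
  out
}
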
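# Support-vector machinery: RBF-kernel C-SVC (one-against-one multi-class
# with Platt-calibrated, pairwise-coupled class probabilities) and
# epsilon-SVR. The duals are solved exactly with quadprog; problem sizes
# here are tens of instances, where an interior QP is as fast as SMO and
# has no tuning state.

#' RBF (Gaussian) kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||x_i - z_j||^2)`.
#'
#' @param x,z Numeric matrices with the same number of columns.
#' @param gamma Positive kernel width parameter.
#' @return `nrow(x)` by `nrow(z)` kernel matrix.
#' @export
rbf_kernel <- function(x, z, gamma) {
  x <- as.matrix(x); z <- as.matrix(z)
  d2 <- outer(rowSums(x^2), rowSums(z^2), `+`) - 2 * tcrossprod(x, z)
  exp(-gamma * pmax(d2, 0))
}

QP_RIDGE <- 1e-6

# Binary C-SVC dual via quadprog; y in {-1, +1}.
svc_fit_binary <- function(x, y, C, gamma) {
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  D <- (y %o% y) * K + diag(QP_RIDGE, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  tol <- 1e-7 * C
  coef <- alpha * y
  f0 <- drop(K %*% coef)
  free <- alpha > tol & alpha < C - tol
  b <- if (any(free)) mean(y[free] - f0[free]) else {
    sv <- alpha > tol
    if (any(sv)) mean(y[sv] - f0[sv]) else mean(y - f0)
  }
  keep <- alpha > tol
  list(sv = x[keep, , drop = FALSE], coef = coef[keep], b = b,
       gamma = gamma, C = C)
}

svc_decision <- function(fit, xnew) {
  drop(rbf_kernel(as.matrix(xnew), fit$sv, fit$gamma) %*% fit$coef) + fit$b
}

# Platt sigmoid calibration (Lin, Lin & Weng's Newton method with
# regularized targets). Returns c(A, B) for P(y=+1|f) = 1/(1+exp(A f + B)).
platt_fit <- function(f, y) {
  prior1 <- sum(y > 0); prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(A, B) {
    fApB <- f * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  Fv <- obj(A, B)
  for (it in 1:100) {
    fApB <- f * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nF <- obj(A + step * dA, B + step * dB)
      if (nF < Fv + 1e-4 * step * gd) {
        A <- A + step * dA; B <- B + step * dB; Fv <- nF
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

platt_predict <- function(f, ab) {
  fApB <- f * ab[["A"]] + ab[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# Pairwise coupling of one-against-one probabilities (Wu, Lin & Weng 2004,
# second method). R[i, j] = estimated P(class i | class i or j, x).
couple_pairwise <- function(R, max_iter = 100, eps = 1e-12) {
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      Q[i, i] <- Q[i, i] + R[j, i]^2
      Q[i, j] <- -R[j, i] * R[i, j]
    }
  }
  p <- rep(1 / k, k)
  for (it in seq_len(max_iter)) {
    Qp <- drop(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps * k) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

#' Train a multi-class SVC with class probabilities
#'
#' One-against-one RBF-kernel C-SVC: one binary machine per unordered class
#' pair, each with a Platt sigmoid fitted to its training decision values;
#' prediction couples the pairwise probabilities into a single probability
#' vector per instance (Wu-Lin-Weng) and labels by its argmax.
#'
#' @param x Numeric feature matrix (rows = instances).
#' @param y Class labels (factor or character); at least two classes, each
#'   with at least 2 instances.
#' @param C,gamma SVM cost and RBF width.
#' @return Object of class `svc_model`.
#' @export
svc_train <- function(x, y, C, gamma) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) {
    stop("invalid input: classification needs at least two classes",
         call. = FALSE)
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[1L], 1, -1)
    fit <- svc_fit_binary(x[sel, , drop = FALSE], yy, C, gamma)
    fit$platt <- platt_fit(svc_decision(fit, x[sel, , drop = FALSE]), yy)
    fit$pair <- pr
    fit
  })
  structure(list(classes = classes, machines = machines,
                 C = C, gamma = gamma),
            class = "svc_model")
}

#' Predict classes and probabilities from a trained SVC
#'
#' @param model An [svc_train()] result.
#' @param xnew Numeric matrix of instances (or a single row vector).
#' @return List with `label` (factor) and `prob` (matrix, one row per
#'   instance, columns in `model$classes` order, rows summing to 1; the
#'   label is the per-row argmax).
#' @export
svc_predict <- function(model, xnew) {
  if (is.null(dim(xnew))) xnew <- matrix(xnew, nrow = 1L)
  k <- length(model$classes)
  n <- nrow(xnew)
  prob <- matrix(0, n, k, dimnames = list(NULL, model$classes))
  R <- array(0.5, dim = c(k, k))
  pair_p <- lapply(model$machines, function(m) {
    platt_predict(svc_decision(m, xnew), m$platt)
  })
  for (r in seq_len(n)) {
    for (mi in seq_along(model$machines)) {
      pr <- model$machines[[mi]]$pair
      i <- match(pr[1L], model$classes)
      j <- match(pr[2L], model$classes)
      pij <- min(max(pair_p[[mi]][r], 1e-7), 1 - 1e-7)
      R[i, j] <- pij
      R[j, i] <- 1 - pij
    }
    prob[r, ] <- couple_pairwise(R)
  }
  label <- factor(model$classes[max.col(prob, ties.method = "first")],
                  levels = model$classes)
  list(label = label, prob = prob)
}

#' Train an epsilon-SVR
#'
#' RBF-kernel epsilon-insensitive support vector regression, solved as the
#' exact 2n-variable dual.
#'
#' @param x Numeric feature matrix.
#' @param y Numeric targets.
#' @param C,gamma Cost and RBF width.
#' @param epsilon Half-width of the insensitive tube, in target units.
#' @return Object of class `svr_model`.
#' @export
svr_train <- function(x, y, C, gamma, epsilon) {
  x <- as.matrix(x)
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(QP_RIDGE, 2 * n)
  d <- c(y - epsilon, -y - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  u <- pmin(pmax(sol$solution, 0), C)
  alpha <- u[1:n]; alpha_star <- u[(n + 1):(2 * n)]
  beta <- alpha - alpha_star
  f0 <- drop(K %*% beta)
  tol <- 1e-7 * C
  free_lo <- alpha > tol & alpha < C - tol        # f(x) = y - eps
  free_hi <- alpha_star > tol & alpha_star < C - tol  # f(x) = y + eps
  b_est <- c(y[free_lo] - f0[free_lo] - epsilon,
             y[free_hi] - f0[free_hi] + epsilon)
  b <- if (length(b_est) > 0L) mean(b_est) else mean(y - f0)
  keep <- abs(beta) > tol
  structure(list(sv = x[keep, , drop = FALSE], coef = beta[keep], b = b,
                 gamma = gamma, C = C, epsilon = epsilon),
            class = "svr_model")
}

#' Predict from a trained epsilon-SVR
#'
#' @param model An [svr_train()] result.
#' @param xnew Numeric matrix (or single row vector).
#' @return Numeric vector of predictions.
#' @export
svr_predict <- function(model, xnew) {
  if (is.null(dim(xnew))) xnew <- matrix(xnew, nrow = 1L)
  if (nrow(model$sv) == 0L) return(rep(model$b, nrow(xnew)))
  drop(rbf_kernel(as.matrix(xnew), model$sv, model$gamma) %*% model$coef) +
    model$b
}

# Deterministic fold assignment, stratified by class for factors.
make_folds <- function(y, k, seed, stratify = is.factor(y) || is.character(y)) {
  n <- length(y)
  if (n < k) stop("fold error: fewer instances than folds", call. = FALSE)
  withr::with_seed(seed, {
    # deal fold ids round-robin over a class-grouped shuffled order: folds
    # stay stratified, globally balanced, and k = n degenerates to LOOCV
    ord <- if (stratify) {
      f <- factor(y)
      unlist(lapply(levels(f), function(lv) {
        idx <- which(f == lv)
        if (length(idx) > 1L) sample(idx) else idx
      }), use.names = FALSE)
    } else {
      sample.int(n)
    }
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(k), n)
    fold
  })
}

#' Exhaustive grid search over SVM hyperparameters
#'
#' Evaluates every grid point by k-fold cross validation and returns the
#' best: highest macro average accuracy for classification, lowest RMSE for
#' regression. Held-out predictions are pooled across folds before scoring.
#' Ties go to the earliest grid point, so the search is deterministic given
#' the seed (which fixes the folds).
#'
#' @param x Feature matrix; `y` class labels (factor/character) for SVC or
#'   numeric targets for SVR.
#' @param y Targets; their type selects the task.
#' @param grid List with numeric components `C`, `gamma` and, for
#'   regression, `epsilon`; the Cartesian product is searched.
#' @param cv_folds Number of folds (default 5); must not exceed n.
#' @param seed Integer seed fixing the fold assignment.
#' @return List with `best` (named list of winning parameters), `score`, and
#'   `table` (a data.frame of all grid points and scores).
#' @export
grid_search <- function(x, y, grid, cv_folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  regression <- is.numeric(y)
  if (nrow(x) < cv_folds) {
    stop("fold error: fewer instances than folds", call. = FALSE)
  }
  pts <- if (regression) {
    expand.grid(C = grid$C, gamma = grid$gamma, epsilon = grid$epsilon,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(C = grid$C, gamma = grid$gamma, KEEP.OUT.ATTRS = FALSE)
  }
  if (nrow(pts) == 0L) stop("invalid argument: empty grid", call. = FALSE)
  fold <- make_folds(y, cv_folds, seed)
  scores <- vapply(seq_len(nrow(pts)), function(g) {
    pred <- if (regression) numeric(length(y)) else
      character(length(y))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      if (regression) {
        m <- svr_train(x[tr, , drop = FALSE], y[tr],
                       pts$C[g], pts$gamma[g], pts$epsilon[g])
        pred[te] <- svr_predict(m, x[te, , drop = FALSE])
      } else {
        m <- svc_train(x[tr, , drop = FALSE], y[tr], pts$C[g], pts$gamma[g])
        pred[te] <- as.character(svc_predict(m, x[te, , drop = FALSE])$label)
      }
    }
    if (regression) {
      sqrt(mean((pred - y)^2))
    } else {
      cc <- confusion_counts(factor(y), factor(pred, levels = levels(factor(y))))
      macro_metrics(cc)[["average_accuracy"]]
    }
  }, numeric(1))
  best <- if (regression) which.min(scores) else which.max(scores)
  list(best = as.list(pts[best, , drop = FALSE]),
       score = scores[best],
       table = cbind(pts, score = scores))
}
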
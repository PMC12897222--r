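# Partial least squares (PLS1, NIPALS) with pooled k-fold RMSECV. This is
# the engine behind all four wavelength selectors; the binary class code
# (healthy = 0, infested = 1) is regressed as a numeric response and
# centered internally.

#' Cross-validation plan
#'
#' Deterministic fold assignment: samples are shuffled with the given seed
#' and dealt round-robin into folds, stratified by class when `y` is binary,
#' so fold sizes differ by at most one and the assignment is reproducible
#' from `(N, n_folds, seed)`.
#'
#' @param n_folds number of folds (>= 2).
#' @param seed integer RNG seed for the shuffle.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_plan")
}

# integer fold id per sample
plan_folds <- function(plan, n, y = NULL) {
  n_folds <- min(plan$n_folds, n)
  folds <- integer(n)
  rng <- local_rng(plan$seed)
  if (!is.null(y) && length(unique(y)) == 2L) {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    idx <- sample.int(n)
    folds[idx] <- rep_len(seq_len(n_folds), n)
  }
  restore_rng(rng)
  folds
}

# seed-scoped RNG helpers: save global state, seed, and restore afterwards,
# so package internals never perturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Core PLS1 fit on centered data. Returns weights W, loadings P, y-loadings
# q, and the effective number of components (early stop when no covariance
# remains). NIPALS for a single response needs no inner iteration: the
# weight vector is X'y normalized.
pls1_core <- function(Xc, yc, A, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < tol) break
    p_a <- crossprod(Xc, t_) / tt
    q_a <- sum(yc * t_) / tt
    Xc <- Xc - t_ %*% t(p_a)
    yc <- yc - q_a * t_
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    a_eff <- a
  }
  list(W = W[, seq_len(max(a_eff, 1L)), drop = FALSE],
       P = P[, seq_len(max(a_eff, 1L)), drop = FALSE],
       q = q[seq_len(max(a_eff, 1L))], A = a_eff)
}

# coefficient vectors on the original (centered) scale for every A = 1..A_eff;
# returns p x A_eff matrix whose column a is b at a components.
pls1_coef_path <- function(core) {
  A <- max(core$A, 1L)
  R <- crossprod(core$P, core$W)  # upper triangular
  Bmat <- matrix(0, nrow(core$W), A)
  for (a in seq_len(A)) {
    alpha <- backsolve(R[seq_len(a), seq_len(a), drop = FALSE],
                       core$q[seq_len(a)])
    Bmat[, a] <- core$W[, seq_len(a), drop = FALSE] %*% alpha
  }
  Bmat
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single numeric response on
#' column-centered data. For binary classification problems the response is
#' the class code (0/1). The regression coefficient vector `b` is returned
#' on the original variable scale with an explicit intercept, so predictions
#' are `X %*% b + intercept`.
#'
#' @param X numeric matrix, N x B.
#' @param y numeric response, length N (class codes 0/1 for selection use).
#' @param A number of latent variables, `1 <= A <= min(N - 1, B)`.
#' @return An object of class `pls_model` with elements `A` (components
#'   actually extracted), `x_mean`, `y_mean`, `W`, `P`, `q`, `b`,
#'   `intercept`.
#' @export
fit_pls <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (var(y) == 0) stop("y has zero variance")
  if (A < 1L || A > min(n - 1L, p)) {
    stop("A must be in 1..min(N-1, B) = 1..", min(n - 1L, p))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  core <- pls1_core(sweep(X, 2L, x_mean), y - y_mean, A)
  if (core$A == 0L) stop("no covariance between X and y: cannot fit")
  b <- pls1_coef_path(core)[, core$A]
  structure(list(A = core$A, x_mean = x_mean, y_mean = y_mean,
                 W = core$W, P = core$P, q = core$q, b = b,
                 intercept = y_mean - sum(x_mean * b)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$b + object$intercept)
}

#' @exportS3Method base::print
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors\n",
              x$A, length(x$b)))
  invisible(x)
}

# Fast internal CV: pooled out-of-fold squared error for A = 1..A_max.
# Returns list(rmsecv = numeric(A_max), best_a). Used by every selector.
pls_cv_curve <- function(X, y, A_max, folds) {
  n <- nrow(X)
  uf <- sort(unique(folds))
  min_train <- n - max(tabulate(folds))
  A_max <- max(1L, min(A_max, min_train - 1L, ncol(X)))
  sse <- numeric(A_max)
  for (f in uf) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    xm <- colMeans(Xtr)
    ym <- mean(ytr)
    if (var(ytr) == 0) {
      warning("fold ", f, " has a single-class training set")
    }
    core <- pls1_core(sweep(Xtr, 2L, xm), ytr - ym, A_max)
    Bmat <- pls1_coef_path(core)
    if (core$A < A_max && core$A >= 1L) {
      Bmat <- Bmat[, c(seq_len(core$A),
                       rep(core$A, A_max - core$A)), drop = FALSE]
    }
    pred <- sweep(X[te, , drop = FALSE], 2L, xm) %*% Bmat + ym
    sse <- sse + colSums((pred - y[te])^2)
  }
  rmsecv <- sqrt(sse / n)
  list(rmsecv = rmsecv, best_a = which.min(rmsecv))
}

#' Cross-validated RMSECV curve
#'
#' For each number of latent variables `A = 1..A_max`, pools the out-of-fold
#' predictions over all folds of the plan and reports the single pooled root
#' mean square error (not the mean of per-fold RMSEs), together with the
#' minimizing `A`.
#'
#' @param X numeric matrix, N x B.
#' @param y numeric response.
#' @param A_max largest number of latent variables to evaluate; capped at
#'   `min(smallest training fold - 1, B)`.
#' @param plan a [cv_plan()].
#' @return A list with `rmsecv` (numeric vector over A), `best_a`, and
#'   `folds` (the fold assignment used).
#' @export
rmsecv <- function(X, y, A_max, plan = cv_plan()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  folds <- plan_folds(plan, nrow(X), y)
  out <- pls_cv_curve(X, y, A_max, folds)
  out$folds <- folds
  out
}
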
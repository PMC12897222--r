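#' Successive projections algorithm (SPA)
#'
#' Forward selection that minimizes collinearity: starting from each
#' candidate column, the chain repeatedly projects all unselected columns
#' onto the orthogonal complement of the span of the selected set and picks
#' the column with the largest residual norm (ties broken by lowest band
#' index). Every candidate subset (start column, chain length in
#' `n_min..n_max`) is scored by PLS RMSECV (or multiple linear regression
#' when `use_mlr = TRUE`) and the global minimizer is returned; RMSECV ties
#' prefer fewer bands, then the lower start index.
#'
#' @param X numeric matrix or [spectra_matrix()].
#' @param y numeric class codes (0/1).
#' @param n_min,n_max smallest/largest chain length considered.
#' @param plan a [cv_plan()].
#' @param max_pc cap on PLS latent variables in the RMSECV scoring.
#' @param starts candidate start columns (default: all).
#' @param use_mlr score subsets with ordinary least squares CV instead of
#'   PLS.
#' @param grid wavelength grid when `X` is a bare matrix.
#' @return A [selection_result()]; the trace records the best (start,
#'   length, RMSECV).
#' @export
select_spa <- function(X, y, n_min = 5L, n_max = NULL, plan = cv_plan(10L),
                       max_pc = 8L, starts = NULL, use_mlr = FALSE,
                       grid = NULL) {
  if (inherits(X, "spectra_matrix")) {
    grid <- X$grid
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  if (is.null(grid)) grid <- wavelength_grid(seq_len(B))
  if (is.null(n_max)) n_max <- min(30L, n - 2L, B)
  n_max <- min(n_max, n - 1L, B)
  n_min <- max(1L, min(n_min, n_max))
  if (is.null(starts)) starts <- seq_len(B)
  folds <- plan_folds(plan, n, y)
  best <- list(rmsecv = Inf, subset = integer(0), start = NA_integer_,
               length = NA_integer_)
  trace <- list()
  for (s in starts) {
    chain <- spa_chain(X, s, n_max)
    for (L in seq(n_min, min(n_max, length(chain)))) {
      sub <- chain[seq_len(L)]
      r <- if (use_mlr) {
        mlr_cv_rmse(X[, sub, drop = FALSE], y, folds)
      } else {
        cv <- pls_cv_curve(X[, sub, drop = FALSE], y, max_pc, folds)
        cv$rmsecv[cv$best_a]
      }
      better <- r < best$rmsecv ||
        (r == best$rmsecv && (L < best$length ||
                              (L == best$length && s < best$start)))
      if (better) {
        best <- list(rmsecv = r, subset = sub, start = s, length = L)
      }
    }
    trace[[length(trace) + 1L]] <- list(start = s,
                                        chain_length = length(chain))
  }
  selection_result("spa", best$subset, grid,
                   trace = c(trace, list(best = best[c("start", "length",
                                                      "rmsecv")])),
                   params = list(n_min = n_min, n_max = n_max,
                                 max_pc = max_pc, use_mlr = use_mlr,
                                 n_folds = plan$n_folds,
                                 best_rmsecv = best$rmsecv))
}

#' SPA projection chain
#'
#' The ordered chain of columns picked by successive orthogonal projections
#' from a given start column. Exposed separately so the projection geometry
#' can be tested against an independent Gram-Schmidt oracle.
#'
#' @param X numeric matrix.
#' @param start start column index.
#' @param n_max maximum chain length.
#' @param tol residual-norm floor; when every remaining column's residual
#'   norm falls below it (collinear exhaustion) the chain is truncated with
#'   a warning.
#' @return Integer vector of column indices, beginning with `start`.
#' @export
spa_chain <- function(X, start, n_max, tol = 1e-12) {
  X <- as.matrix(X)
  B <- ncol(X)
  n_max <- min(n_max, B)
  V <- X
  chain <- integer(n_max)
  chain[1L] <- start
  picked <- start
  for (step in seq_len(n_max - 1L)) {
    v_sel <- V[, picked]
    nv <- sum(v_sel^2)
    if (nv > 0) {
      # project the last selected column out of every column (MGS update)
      V <- V - v_sel %*% (crossprod(v_sel, V) / nv)
    }
    norms <- sqrt(colSums(V^2))
    norms[chain[seq_len(step)]] <- -1
    mx <- max(norms)
    if (mx < tol) {
      warning("collinear exhaustion: SPA chain truncated at length ", step)
      return(chain[seq_len(step)])
    }
    # lowest index among ties (within relative tolerance)
    cand <- which(norms >= mx * (1 - 1e-9))
    picked <- cand[1L]
    chain[step + 1L] <- picked
  }
  chain
}

# k-fold CV RMSE of ordinary least squares (intercept included)
mlr_cv_rmse <- function(X, y, folds) {
  n <- nrow(X)
  sse <- 0
  for (f in sort(unique(folds))) {
    te <- folds == f
    Xtr <- cbind(1, X[!te, , drop = FALSE])
    fit <- lm.fit(Xtr, y[!te])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred <- cbind(1, X[te, , drop = FALSE]) %*% cf
    sse <- sse + sum((pred - y[te])^2)
  }
  sqrt(sse / n)
}
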
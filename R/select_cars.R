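#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo wavelength selection driven by PLS regression coefficients.
#' Each run fits a PLS model (latent variables chosen by RMSECV, capped at
#' `max_pc`) on a random subset of the samples, weights every surviving band
#' by its normalized absolute coefficient, enforces the exponentially
#' decreasing retention schedule `r_i = a * exp(-k * i)` (with `r_1 = 1` and
#' `r_N = 2/B`, so the enforced count at run `i` is `ceiling(B * r_i)`),
#' then applies adaptive reweighted sampling (weighted draws with
#' replacement, unique survivors, truncated to the enforced count by
#' descending weight). The surviving set of each run is scored by RMSECV on
#' the full calibration set; the globally best-scoring set wins.
#'
#' @param X numeric matrix or [spectra_matrix()].
#' @param y numeric class codes (0/1).
#' @param n_runs number of Monte-Carlo sampling runs.
#' @param max_pc cap on PLS latent variables.
#' @param plan a [cv_plan()] for all RMSECV evaluations.
#' @param mc_fraction fraction of samples drawn per run.
#' @param seed RNG seed.
#' @param grid wavelength grid when `X` is a bare matrix.
#' @return A [selection_result()] with a per-run trace (`run`, `n_vars`,
#'   `rmsecv`, `best_a`).
#' @export
select_cars <- function(X, y, n_runs = 50L, max_pc = 8L,
                        plan = cv_plan(10L), mc_fraction = 0.8,
                        seed = 1L, grid = NULL) {
  if (inherits(X, "spectra_matrix")) {
    grid <- X$grid
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  B <- ncol(X)
  n <- nrow(X)
  if (B < 2L) stop("CARS needs at least 2 bands")
  if (is.null(grid)) grid <- wavelength_grid(seq_len(B))
  sched <- cars_schedule(B, n_runs)
  folds <- plan_folds(plan, n, y)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  current <- seq_len(B)
  trace <- vector("list", n_runs)
  best_rmsecv <- Inf
  best_set <- current
  n_mc <- max(2L, floor(mc_fraction * n))
  for (i in seq_len(n_runs)) {
    if (length(current) < 2L) break
    rows <- sort(sample.int(n, n_mc))
    Xmc <- X[rows, current, drop = FALSE]
    ymc <- y[rows]
    mc_folds <- rep_len(seq_len(min(plan$n_folds, n_mc)), n_mc)
    cv_mc <- pls_cv_curve(Xmc, ymc, max_pc, mc_folds)
    fit <- fit_pls(Xmc, ymc, cv_mc$best_a)
    w <- abs(fit$b)
    w <- w / sum(w)
    n_keep <- min(sched$count[i], length(current))
    # adaptive reweighted sampling: weighted draws, unique survivors,
    # truncated to the enforced count by descending weight
    draws <- sample.int(length(current), size = n_keep * 5L,
                        replace = TRUE, prob = w)
    surv <- unique(draws)
    if (length(surv) > n_keep) {
      surv <- surv[order(w[surv], decreasing = TRUE)][seq_len(n_keep)]
    }
    current <- sort(current[surv])
    if (length(current) < 2L) {
      trace[[i]] <- list(run = i, n_vars = length(current),
                         rmsecv = NA_real_, best_a = NA_integer_)
      break
    }
    cv <- pls_cv_curve(X[, current, drop = FALSE], y, max_pc, folds)
    r <- cv$rmsecv[cv$best_a]
    trace[[i]] <- list(run = i, n_vars = length(current), rmsecv = r,
                       best_a = cv$best_a)
    if (r < best_rmsecv) {
      best_rmsecv <- r
      best_set <- current
    }
  }
  selection_result("cars", best_set, grid,
                   trace = trace[!vapply(trace, is.null, logical(1))],
                   seed = seed,
                   params = list(n_runs = n_runs, max_pc = max_pc,
                                 n_folds = plan$n_folds,
                                 mc_fraction = mc_fraction,
                                 best_rmsecv = best_rmsecv))
}

#' CARS enforced-retention schedule
#'
#' Closed-form exponentially decreasing retention: `r_i = a * exp(-k * i)`
#' with `r_1 = 1` and `r_N = 2/B`, so `k = log(B/2) / (N - 1)` and
#' `a = exp(k)`. The enforced variable count at run `i` is
#' `ceiling(B * r_i)`: all `B` bands at run 1 and 2 bands at run `N`.
#'
#' @param B number of bands.
#' @param n_runs number of Monte-Carlo runs `N`.
#' @return A list with `ratio` (numeric) and `count` (integer), both length
#'   `n_runs`.
#' @export
cars_schedule <- function(B, n_runs) {
  if (n_runs < 2L) stop("n_runs must be >= 2")
  k <- log(B / 2) / (n_runs - 1)
  a <- exp(k)
  i <- seq_len(n_runs)
  ratio <- a * exp(-k * i)
  # tiny slack so B * r_N = 2 does not round up to 3 through float error
  list(ratio = ratio, count = as.integer(ceiling(B * ratio - 1e-9)))
}
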
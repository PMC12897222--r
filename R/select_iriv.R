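#' Iteratively retained informative variables (IRIV)
#'
#' Each iteration draws a binary inclusion matrix (rows = random variable
#' subsets with inclusion probability 0.5), computes the RMSECV of a PLS
#' model for every row, and classifies each variable by comparing the
#' RMSECV distribution of rows that exclude it against rows that include
#' it: `DMEAN = mean(excluding) - mean(including)`, with a Wilcoxon
#' rank-sum p-value. Variables with `DMEAN > 0` are strongly (`p < alpha`)
#' or weakly (`p >= alpha`) informative and are retained; uninformative and
#' interfering variables are dropped. Iterations continue until nothing is
#' dropped, then a final backward elimination removes any variable whose
#' removal lowers the RMSECV of the retained set.
#'
#' @param X numeric matrix or [spectra_matrix()].
#' @param y numeric class codes (0/1).
#' @param max_pc cap on PLS latent variables.
#' @param plan a [cv_plan()] (11-fold by default).
#' @param m_rows rows of the binary inclusion matrix per iteration.
#' @param alpha significance level of the rank-sum test.
#' @param seed RNG seed.
#' @param record_matrices keep each iteration's binary matrix and row
#'   RMSECVs in the trace (for auditing; memory-heavy on wide data).
#' @param grid wavelength grid when `X` is a bare matrix.
#' @return A [selection_result()]; empty (with a warning) when no variable
#'   survives.
#' @export
select_iriv <- function(X, y, max_pc = 40L, plan = cv_plan(11L),
                        m_rows = 500L, alpha = 0.05, seed = 1L,
                        record_matrices = FALSE, grid = NULL) {
  if (inherits(X, "spectra_matrix")) {
    grid <- X$grid
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  if (is.null(grid)) grid <- wavelength_grid(seq_len(B))
  if (m_rows < 50L) stop("m_rows must be >= 50")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  folds <- plan_folds(plan, n, y)
  current <- seq_len(B)
  trace <- list()
  repeat {
    p_cur <- length(current)
    if (p_cur == 0L) break
    if (p_cur == 1L) break
    M <- matrix(rbinom(m_rows * p_cur, 1L, 0.5) == 1L, m_rows, p_cur)
    # guard degenerate rows/columns so both comparison groups exist
    rs <- rowSums(M)
    M[rs < 2L, ] <- TRUE
    cs <- colSums(M)
    M[1L, cs == 0L] <- TRUE
    M[2L, cs == m_rows] <- FALSE
    rmse_rows <- numeric(m_rows)
    for (r in seq_len(m_rows)) {
      sub <- which(M[r, ])
      cv <- pls_cv_curve(X[, current[sub], drop = FALSE], y, max_pc, folds)
      rmse_rows[r] <- cv$rmsecv[cv$best_a]
    }
    cls <- iriv_classify(M, rmse_rows, alpha)
    retained <- which(cls %in% c("strong", "weak"))
    trace[[length(trace) + 1L]] <- c(
      list(n_vars = p_cur, n_retained = length(retained),
           classes = table(factor(cls, levels = c("strong", "weak",
                                                  "uninformative",
                                                  "interfering")))),
      if (record_matrices) list(M = M, rmse_rows = rmse_rows,
                                variables = current, classification = cls))
    if (length(retained) == 0L) {
      warning("IRIV retained no variables (all-noise input)")
      restore_rng(old)
      on.exit()
      return(selection_result("iriv", integer(0), grid, trace = trace,
                              seed = seed,
                              params = list(max_pc = max_pc,
                                            n_folds = plan$n_folds,
                                            m_rows = m_rows, alpha = alpha)))
    }
    if (length(retained) == p_cur) break  # all retained strong/weak: stop
    current <- current[retained]
  }
  # backward elimination: drop any variable whose removal lowers RMSECV
  if (length(current) > 1L) {
    repeat {
      cv <- pls_cv_curve(X[, current, drop = FALSE], y, max_pc, folds)
      base_rmse <- cv$rmsecv[cv$best_a]
      drop_rmse <- vapply(seq_along(current), function(j) {
        sub <- current[-j]
        cvj <- pls_cv_curve(X[, sub, drop = FALSE], y, max_pc, folds)
        cvj$rmsecv[cvj$best_a]
      }, numeric(1))
      if (min(drop_rmse) < base_rmse && length(current) > 1L) {
        current <- current[-which.min(drop_rmse)]
        trace[[length(trace) + 1L]] <- list(backward_drop = TRUE,
                                            n_vars = length(current),
                                            rmsecv = min(drop_rmse))
      } else {
        break
      }
    }
  }
  selection_result("iriv", current, grid, trace = trace, seed = seed,
                   params = list(max_pc = max_pc, n_folds = plan$n_folds,
                                 m_rows = m_rows, alpha = alpha))
}

#' Classify variables from a binary inclusion matrix
#'
#' Given the binary inclusion matrix and the per-row RMSECVs of one IRIV
#' iteration, classifies each variable as `strong`, `weak`,
#' `uninformative` or `interfering`. Exposed so the classification can be
#' audited against an independent recomputation.
#'
#' @param M logical matrix, rows = subsets, columns = variables.
#' @param rmse_rows numeric RMSECV per row of `M`.
#' @param alpha rank-sum significance level.
#' @return Character vector, one class per column of `M`.
#' @export
iriv_classify <- function(M, rmse_rows, alpha = 0.05) {
  vapply(seq_len(ncol(M)), function(j) {
    incl <- rmse_rows[M[, j]]
    excl <- rmse_rows[!M[, j]]
    if (length(incl) == 0L || length(excl) == 0L) return("uninformative")
    dmean <- mean(excl) - mean(incl)
    p <- suppressWarnings(wilcox.test(excl, incl, exact = FALSE)$p.value)
    if (dmean > 0) {
      if (p < alpha) "strong" else "weak"
    } else {
      if (p < alpha) "interfering" else "uninformative"
    }
  }, character(1))
}
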
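#' Uninformative variable elimination (UVE)
#'
#' Augments the spectra with artificial noise columns (uniform, scaled to
#' `1e-10` of the data magnitude), refits a PLS model once per deletion
#' group (the folds of `plan`; set `n_folds = N` for leave-one-out), and
#' scores every variable by its coefficient stability
#' `c_j = mean(b_j) / sd(b_j)` across the refits. The symmetric threshold is
#' the stated quantile of `|c|` over the noise columns; real variables whose
#' `|c_j|` exceeds it are retained.
#'
#' @param X numeric matrix or [spectra_matrix()].
#' @param y numeric class codes (0/1).
#' @param max_pc cap on PLS latent variables; the component count is chosen
#'   once by RMSECV on the augmented data, then held fixed for the refits.
#' @param plan a [cv_plan()] defining the deletion groups.
#' @param noise_count number of artificial noise columns (default `B`).
#' @param threshold_quantile quantile of noise `|c|` used as the cutoff.
#' @param seed RNG seed.
#' @param record_matrices keep the augmented matrix, deletion-group
#'   assignment and per-group coefficient matrix in the trace (for
#'   auditing; memory-heavy on wide data).
#' @param grid wavelength grid when `X` is a bare matrix.
#' @return A [selection_result()]; the trace stores the stability vector,
#'   the threshold and the chosen component count.
#' @export
select_uve <- function(X, y, max_pc = 8L, plan = cv_plan(10L),
                       noise_count = NULL, threshold_quantile = 0.99,
                       seed = 1L, record_matrices = FALSE, grid = NULL) {
  if (inherits(X, "spectra_matrix")) {
    grid <- X$grid
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  if (is.null(grid)) grid <- wavelength_grid(seq_len(B))
  if (is.null(noise_count)) noise_count <- B
  if (noise_count < 1L) stop("noise_count must be >= 1")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  noise <- matrix(runif(n * noise_count), n, noise_count) *
    (1e-10 * max(abs(X)))
  Xa <- cbind(X, noise)
  folds <- plan_folds(plan, n, y)
  cv <- pls_cv_curve(Xa, y, max_pc, folds)
  A <- cv$best_a
  groups <- sort(unique(folds))
  coefs <- matrix(NA_real_, length(groups), ncol(Xa))
  for (g in seq_along(groups)) {
    keep <- folds != groups[g]
    fit <- fit_pls(Xa[keep, , drop = FALSE], y[keep], A)
    coefs[g, ] <- fit$b
  }
  mu <- colMeans(coefs)
  sdev <- apply(coefs, 2L, sd)
  stability <- mu / sdev
  stability[sdev == 0] <- Inf  # perfectly stable coefficient: always kept
  noise_c <- abs(stability[(B + 1L):(B + noise_count)])
  threshold <- as.numeric(quantile(noise_c[is.finite(noise_c)],
                                   threshold_quantile))
  keep_idx <- which(abs(stability[seq_len(B)]) > threshold)
  selection_result("uve", keep_idx, grid,
                   trace = list(c(
                     list(stability = stability[seq_len(B)],
                          noise_stability = stability[-seq_len(B)],
                          threshold = threshold, A = A),
                     if (record_matrices) list(X_augmented = Xa,
                                               folds = folds,
                                               coefs = coefs))),
                   seed = seed,
                   params = list(max_pc = max_pc, n_folds = plan$n_folds,
                                 noise_count = noise_count,
                                 threshold_quantile = threshold_quantile))
}
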
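# Shared fixtures for the suite. Everything is generated in code; the
# planted-band configurations below pin the class effect to exactly one
# grid band per window so selector recovery can be scored unambiguously.

# 256-band config with 10 single-band effect windows inside the three
# discriminative regions (980-1100, 1200-1300, 1400-1600 nm)
planted_bands_256 <- c(45L, 55L, 65L, 110L, 120L, 130L, 175L, 190L, 205L, 220L)

recovery_config_256 <- function(seed, amplitude = 0.02, ...) {
  g <- default_wavelength_grid()
  wl <- as.numeric(g)
  wins <- lapply(planted_bands_256,
                 function(i) c(wl[i] - 2, wl[i] + 2, amplitude))
  synth_config(grid = g, effect_windows = wins, seed = seed, ...)
}

# 30-band config with 5 single-band windows, balanced classes of 100
planted_bands_30 <- c(5L, 10L, 15L, 20L, 25L)

recovery_config_30 <- function(seed, amplitude = 0.02, ...) {
  g <- wavelength_grid(seq(850, 1700, length.out = 30))
  wl <- as.numeric(g)
  wins <- lapply(planted_bands_30,
                 function(i) c(wl[i] - 10, wl[i] + 10, amplitude))
  synth_config(n_healthy = 100L, n_infested = 100L, grid = g,
               effect_windows = wins, seed = seed, ...)
}

# independent from-scratch confusion-matrix metrics (oracle)
oracle_metrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  acc <- (tp + tn) / n
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  po <- acc
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  list(acc = acc, precision = prec, recall = rec,
       f1 = 2 * prec * rec / (prec + rec),
       kappa = if (pe == 1) (if (po == 1) 1 else 0) else (po - pe) / (1 - pe))
}

# independent O(N^2) maximin Kennard-Stone (oracle)
oracle_kennard_stone <- function(X, n_train) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- sort(c(idx[1, 1], idx[1, 2]))
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(j) min(D[j, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  sort(sel)
}

# independent SPA chain oracle: explicit projection onto the orthogonal
# complement of the selected columns' span via QR at every step
oracle_spa_chain <- function(X, start, n_max) {
  chain <- start
  for (step in seq_len(n_max - 1)) {
    Q <- qr.Q(qr(X[, chain, drop = FALSE]))
    R <- X - Q %*% (t(Q) %*% X)
    norms <- sqrt(colSums(R^2))
    norms[chain] <- -1
    chain <- c(chain, which.max(norms))
  }
  chain
}

# default train/test pipeline used by several tests: preprocess (train-only
# state), select on train, classify, evaluate
run_one_combo <- function(sp, preproc, selector, clf, seed = 1L) {
  split <- kennard_stone_split(sp, 0.7)
  tr <- split$train_ids
  te <- split$test_ids
  ptr <- apply_preprocess(sp[tr, ], preproc)
  pte <- apply_preprocess(sp[te, ], preproc, state = attr(ptr, "state"))
  sel <- run_selector(ptr$X, sp$labels[tr], selector, grid = sp$grid,
                      seed = seed)
  bands <- sel$selected
  model <- tune_and_train(ptr$X[, bands, drop = FALSE], sp$labels[tr], clf)
  evaluate_model(model, pte$X[, bands, drop = FALSE], sp$labels[te])
}
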
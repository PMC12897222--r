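test_that("CARS retention schedule matches the exponential closed form", {
  B <- 256; N <- 50
  s <- cars_schedule(B, N)
  k <- log(B / 2) / (N - 1)
  a <- exp(k)
  for (i in seq_len(N)) {
    expect_equal(s$ratio[i], a * exp(-k * i), tolerance = 1e-12)
    expect_identical(s$count[i], as.integer(ceiling(B * a * exp(-k * i) -
                                                      1e-9)))
  }
  expect_identical(s$count[1], 256L)   # ratio 1 by construction
  expect_identical(s$count[N], 2L)     # r_N = 2/B
  s2 <- cars_schedule(100, 30)
  expect_identical(s2$count[1], 100L)
  expect_identical(s2$count[30], 2L)
})

test_that("CARS is reproducible and its trace shrinks with the schedule", {
  set.seed(61)
  X <- matrix(rnorm(60 * 40), 60, 40)
  y <- as.numeric(X[, c(3, 17)] %*% c(1, -1)) + rnorm(60, 0, 0.3)
  r1 <- select_cars(X, y, n_runs = 15, plan = cv_plan(5), seed = 5)
  r2 <- select_cars(X, y, n_runs = 15, plan = cv_plan(5), seed = 5)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
  sizes <- vapply(r1$trace, function(t) t$n_vars, numeric(1))
  sched <- cars_schedule(40, 15)$count
  expect_true(all(sizes <= sched[seq_along(sizes)]))
})

test_that("SPA orders orthogonal columns by decreasing norm", {
  # orthogonal columns: projection is a no-op, so the chain after the start
  # is simply the remaining columns sorted by norm
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20, 5)))
  scales <- c(3, 1, 4, 2, 5)
  X <- Q %*% diag(scales)
  for (start in 1:5) {
    chain <- spa_chain(X, start, 5)
    expect_identical(chain[-1], setdiff(order(-scales), start))
  }
})

test_that("SPA residual-norm ties are broken by the lowest index", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  X <- cbind(e1, e2, e1 + e2)
  # starting at column 3: residuals of e1 and e2 both have norm 1/sqrt(2)
  chain <- spa_chain(X, 3L, 2L)
  expect_identical(chain, c(3L, 1L))
})

test_that("SPA chains equal an independent Gram-Schmidt oracle", {
  for (s in 1:20) {
    set.seed(700 + s)
    X <- matrix(rnorm(30 * 20), 30, 20)
    start <- sample(20, 1)
    expect_identical(spa_chain(X, start, 12L),
                     as.integer(oracle_spa_chain(X, start, 12L)))
  }
})

test_that("SPA selection is unchanged by duplicating all rows", {
  set.seed(62)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(25, 0.2)
  for (start in c(1, 7)) {
    expect_identical(spa_chain(X, start, 8L),
                     spa_chain(rbind(X, X) / sqrt(2), start, 8L))
  }
})

test_that("SPA returns the RMSECV-minimizing (start, length) subset", {
  set.seed(63)
  t_ <- rnorm(80)
  X <- cbind(t_ + rnorm(80, 0, 0.05), matrix(rnorm(80 * 7), 80, 7))
  y <- t_
  r <- select_spa(X, y, n_min = 1, n_max = 4, plan = cv_plan(5))
  expect_true(1L %in% r$selected)  # the informative column must be kept
  expect_true(length(r$selected) <= 4)
})

test_that("UVE stability equals an independent per-group refit loop", {
  set.seed(64)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- as.numeric(X[, c(2, 8)] %*% c(1.5, -1)) + rnorm(60, 0, 0.3)
  r <- select_uve(X, y, max_pc = 3, plan = cv_plan(5), noise_count = 10,
                  seed = 3, record_matrices = TRUE)
  tr <- r$trace[[1]]
  Xa <- tr$X_augmented
  manual <- matrix(NA_real_, length(unique(tr$folds)), ncol(Xa))
  for (g in sort(unique(tr$folds))) {
    keep <- tr$folds != g
    manual[g, ] <- fit_pls(Xa[keep, ], y[keep], tr$A)$b
  }
  stab <- colMeans(manual) / apply(manual, 2, sd)
  expect_equal(tr$stability, stab[1:10], tolerance = 1e-10)
  expect_equal(tr$noise_stability, stab[11:20], tolerance = 1e-10)
})

test_that("UVE keeps planted bands and drops noise on independent columns", {
  hits <- logical(0)
  for (s in 1:5) {
    set.seed(900 + s)
    X <- matrix(rnorm(200 * 60), 200, 60)
    y <- as.numeric(X[, c(10, 50)] %*% c(1, 1)) + rnorm(200, 0, 0.5)
    r <- select_uve(X, y, max_pc = 5, seed = s)
    hits <- c(hits, all(c(10L, 50L) %in% r$selected))
  }
  expect_gte(mean(hits), 0.8)
})

test_that("UVE retains almost nothing when y is pure noise", {
  fracs <- sapply(1:10, function(s) {
    set.seed(920 + s)
    X <- matrix(rnorm(150 * 40), 150, 40)
    y <- rnorm(150)
    # 200 noise columns so the 0.99 threshold quantile is well estimated
    length(select_uve(X, y, max_pc = 3, noise_count = 200,
                      seed = s)$selected) / 40
  })
  expect_lte(mean(fracs), 2 * (1 - 0.99))
})

test_that("IRIV classification is recomputable from the recorded matrix", {
  set.seed(65)
  cfg <- recovery_config_30(seed = 65)
  gen <- generate_spectra(cfg)
  X <- gen$spectra$X[, 1:8]
  y <- gen$truth$labels
  r <- select_iriv(X, y, max_pc = 5, plan = cv_plan(5), m_rows = 60,
                   seed = 8, record_matrices = TRUE)
  tr <- r$trace[[1]]
  expect_false(is.null(tr$M))
  for (j in seq_len(ncol(tr$M))) {
    incl <- tr$rmse_rows[tr$M[, j]]
    excl <- tr$rmse_rows[!tr$M[, j]]
    dmean <- mean(excl) - mean(incl)
    p <- suppressWarnings(wilcox.test(excl, incl, exact = FALSE)$p.value)
    expected <- if (dmean > 0) {
      if (p < 0.05) "strong" else "weak"
    } else {
      if (p < 0.05) "interfering" else "uninformative"
    }
    expect_identical(tr$classification[j], expected)
  }
})

test_that("IRIV retained sets shrink monotonically and terminate", {
  set.seed(66)
  X <- matrix(rnorm(120 * 12), 120, 12)
  y <- as.numeric(X[, c(3, 9)] %*% c(1, 1)) + rnorm(120, 0, 0.4)
  r <- select_iriv(X, y, max_pc = 5, plan = cv_plan(5), m_rows = 80,
                   seed = 2)
  sizes <- vapply(r$trace, function(t) {
    if (!is.null(t$n_vars)) t$n_vars else NA_real_
  }, numeric(1))
  sizes <- sizes[!is.na(sizes)]
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(c(3L, 9L) %in% r$selected))
})

test_that("IRIV recovers planted bands among a handful of variables", {
  recovered <- sapply(1:3, function(s) {
    cfg <- recovery_config_30(seed = s)
    gen <- generate_spectra(cfg)
    # 8-band sub-problem holding 2 planted bands (indices 5 and 10 -> 1, 6)
    X <- gen$spectra$X[, 3:10]
    sel <- select_iriv(X, gen$truth$labels, max_pc = 5, plan = cv_plan(5),
                       m_rows = 100, seed = s)$selected
    all(c(3L, 8L) %in% sel)  # bands 5 and 10 within the 3:10 window
  })
  expect_gte(mean(recovered), 2 / 3)
})

test_that("chaining SPA restricts and re-maps the first-stage selection", {
  set.seed(67)
  cfg <- recovery_config_30(seed = 67)
  gen <- generate_spectra(cfg)
  X <- gen$spectra$X
  y <- gen$truth$labels
  first <- select_cars(X, y, n_runs = 12, plan = cv_plan(5), seed = 4,
                       grid = gen$spectra$grid)
  chained <- select_chain(first, X, y, grid = gen$spectra$grid,
                          selector = "spa", n_min = 2, n_max = 6,
                          plan = cv_plan(5))
  expect_true(all(chained$selected %in% first$selected))
  expect_lte(length(chained$selected), length(first$selected))
  expect_identical(chained$method, "cars_spa")
  ident <- select_chain(first, X, y, grid = gen$spectra$grid,
                        selector = "identity")
  expect_identical(ident$selected, first$selected)
  empty <- selection_result("cars", integer(0), gen$spectra$grid)
  expect_error(select_chain(empty, X, y), "empty")
})

test_that("selection tables report method, count and wavelengths", {
  g <- wavelength_grid(seq(850, 1700, length.out = 10))
  r1 <- selection_result("cars", c(2L, 5L), g)
  r2 <- selection_result("uve", c(1L, 5L, 9L), g)
  p <- tempfile(fileext = ".csv")
  tab <- selection_table(r1, r2, path = p)
  expect_identical(tab$method, c("cars", "uve"))
  expect_identical(tab$n_bands, c(2L, 3L))
  expect_match(tab$bands_nm[1], "^944.4 1227.8$")
  expect_true(file.exists(p))
})

test_that("selector specs dispatch to the same results as direct calls", {
  set.seed(68)
  cfg <- recovery_config_30(seed = 68)
  gen <- generate_spectra(cfg)
  X <- gen$spectra$X
  y <- gen$truth$labels
  direct <- select_cars(X, y, n_runs = 10, plan = cv_plan(5), seed = 9,
                        grid = gen$spectra$grid)
  via_spec <- run_selector(X, y, selector_spec("cars", n_runs = 10,
                                               plan = cv_plan(5)),
                           grid = gen$spectra$grid, seed = 9)
  expect_identical(direct$selected, via_spec$selected)
  keep_all <- run_selector(X, y, selector_spec("none"),
                           grid = gen$spectra$grid)
  expect_identical(keep_all$selected, seq_len(ncol(X)))
})
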
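make_sm <- function(X, wl = NULL) {
  if (is.null(wl)) wl <- seq(1000, by = 10, length.out = ncol(X))
  spectra_matrix(X, wavelength_grid(wl))
}

test_that("SNV maps [2,4,6] to [-1,0,1] and normalizes every row exactly", {
  sm <- make_sm(rbind(c(2, 4, 6), c(1, 5, 3)))
  out <- snv(sm)
  expect_equal(unname(out$X[1, ]), c(-1, 0, 1))
  expect_lt(max(abs(rowMeans(out$X))), 1e-12)
  expect_lt(max(abs(apply(out$X, 1, sd) - 1)), 1e-12)
  # idempotence and affine invariance (b > 0)
  expect_equal(snv(out)$X, out$X, tolerance = 1e-12)
  distorted <- make_sm(3.7 + 1.9 * sm$X)
  expect_equal(snv(distorted)$X, out$X, tolerance = 1e-12)
  expect_error(snv(make_sm(rbind(c(1, 1, 1)))), "zero-variance")
})

test_that("MSC inverts affine distortion of the reference exactly", {
  set.seed(7)
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  X <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  out <- msc(make_sm(X), reference = ref)
  cf <- attr(out, "coef")
  expect_equal(unname(out$X[1, ]), ref, tolerance = 1e-12)
  expect_equal(unname(cf[1, ]), c(0, 1), tolerance = 1e-12)
  expect_equal(unname(out$X[2, ]), ref, tolerance = 1e-12)
  expect_equal(unname(cf[2, ]), c(3, 2), tolerance = 1e-12)
  expect_equal(unname(cf[3, ]), c(-1, 0.5), tolerance = 1e-12)
})

test_that("MSC coefficients match an independent two-parameter OLS oracle", {
  set.seed(8)
  X <- matrix(runif(6 * 25), 6, 25)
  out <- msc(make_sm(X))
  ref <- colMeans(X)
  cf <- attr(out, "coef")
  for (i in 1:6) {
    o <- lm(X[i, ] ~ ref)
    expect_equal(unname(cf[i, ]), unname(coef(o)), tolerance = 1e-10)
    expect_equal(unname(out$X[i, ]), unname((X[i, ] - coef(o)[1]) / coef(o)[2]),
                 tolerance = 1e-10)
  }
})

test_that("MSC reuses a frozen training reference on new spectra", {
  set.seed(9)
  Xtr <- matrix(runif(8 * 20), 8, 20)
  Xte <- matrix(runif(4 * 20), 4, 20)
  tr <- apply_preprocess(make_sm(Xtr), preprocess_spec("msc"))
  te <- apply_preprocess(make_sm(Xte), preprocess_spec("msc"),
                         state = attr(tr, "state"))
  expect_equal(attr(te, "reference"), colMeans(Xtr))
  direct <- msc(make_sm(Xte), reference = colMeans(Xtr))
  expect_equal(te$X, direct$X)
})

test_that("SG smoothing reproduces low-order polynomials at interior points", {
  wl <- seq(1000, 1500, length.out = 60)
  x <- 2 + 0.03 * wl - 1e-5 * wl^2  # degree 2 = polyorder
  sm <- make_sm(rbind(x), wl)
  out <- sg_smooth(sm, window = 11, polyorder = 2)
  interior <- 6:55
  expect_lt(max(abs(out$X[1, interior] - x[interior])), 1e-10)
  cst <- sg_smooth(make_sm(rbind(rep(4, 60)), wl), 11, 2)
  expect_equal(unname(cst$X[1, ]), rep(4, 60), tolerance = 1e-12)
  expect_error(sg_smooth(sm, window = 10, polyorder = 2), "odd")
  expect_error(sg_smooth(sm, window = 3, polyorder = 3), "polyorder")
})

test_that("SG smoothing matches a brute-force local regression oracle", {
  set.seed(12)
  wl <- seq(900, 1300, length.out = 41)
  x <- runif(41)
  out <- sg_smooth(make_sm(rbind(x), wl), window = 9, polyorder = 3)
  half <- 4
  for (i in c(1, 3, 5, 21, 38, 41)) {  # edges and interior
    lo <- max(1, i - half); hi <- min(41, i + half)
    off <- (lo:hi) - i
    fit <- lm(x[lo:hi] ~ poly(off, 3, raw = TRUE))
    expect_equal(out$X[1, i], unname(predict(fit)[which(off == 0)]),
                 tolerance = 1e-9)
  }
})

test_that("SG smoothing is a linear operator", {
  set.seed(13)
  x <- runif(30); y <- runif(30)
  s <- function(v) sg_smooth(matrix(v, 1), 7, 2)[1, ]
  expect_equal(s(2.5 * x - 1.25 * y), 2.5 * s(x) - 1.25 * s(y),
               tolerance = 1e-12)
})

test_that("SG derivatives are scaled per nm and exact on ramps", {
  wl <- seq(1000, 1590, by = 10)  # step 10 nm
  B <- length(wl)
  ramp <- 2 * wl
  d1 <- sg_derivative(make_sm(rbind(ramp), wl), 11, 2, order = 1)
  interior <- 6:(B - 5)
  expect_lt(max(abs(d1$X[1, interior] - 2)), 1e-9)
  quad <- wl^2
  d2 <- sg_derivative(make_sm(rbind(quad), wl), 11, 2, order = 2)
  expect_lt(max(abs(d2$X[1, interior] - 2)), 1e-7)
  expect_error(sg_derivative(make_sm(rbind(ramp), wl), 11, 1, order = 2),
               ">=")
})

test_that("SG interior points agree with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(14)
  x <- runif(50)
  ours <- sg_smooth(matrix(x, 1), window = 11, polyorder = 2)[1, ]
  theirs <- signal::sgolayfilt(x, p = 2, n = 11)
  interior <- 6:45
  expect_equal(ours[interior], theirs[interior], tolerance = 1e-10)
})

test_that("detrend annihilates polynomials of the fitted order", {
  wl <- seq(850, 1700, length.out = 50)
  p2 <- 1 + 0.002 * wl - 3e-6 * wl^2
  out <- detrend(make_sm(rbind(p2), wl), polyorder = 2)
  expect_lt(max(abs(out$X)), 1e-9)
  # invariance: detrend(x + p(wl)) = detrend(x)
  set.seed(15)
  x <- runif(50)
  a <- detrend(make_sm(rbind(x), wl), 2)$X
  b <- detrend(make_sm(rbind(x + p2), wl), 2)$X
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("detrend equals x minus an independent polynomial regression fit", {
  set.seed(16)
  wl <- seq(850, 1700, length.out = 40)
  x <- runif(40)
  out <- detrend(make_sm(rbind(x), wl), polyorder = 3)
  fit <- lm(x ~ poly(wl, 3, raw = TRUE))
  expect_equal(unname(out$X[1, ]), unname(x - fitted(fit)), tolerance = 1e-8)
})

test_that("baseline correction flattens constants and preserves narrow peaks", {
  wl <- seq(850, 1700, length.out = 120)
  cst <- rep(5, 120)
  out <- baseline_correct(make_sm(rbind(cst), wl))
  expect_lt(max(abs(out$X)), 1e-3 * 5)
  # narrow Gaussian peak on a flat base: height preserved within 5%
  peak <- 0.5 * exp(-((wl - 1200) / 12)^2)
  spec <- 2 + peak
  out2 <- baseline_correct(make_sm(rbind(spec), wl))
  expect_equal(max(out2$X[1, ]), 0.5, tolerance = 0.05)
  # asymmetry: small p pushes the baseline under the noise cloud, so far
  # more points lie above it than with symmetric weights, and the points
  # it does overshoot are overshot by less than the noise scale
  set.seed(17)
  noisy <- 2 + peak + abs(rnorm(120, 0, 0.02))
  bl_asym <- attr(baseline_correct(make_sm(rbind(noisy), wl), lambda = 100,
                                   p_asym = 0.01), "baseline")[1, ]
  bl_sym <- attr(baseline_correct(make_sm(rbind(noisy), wl), lambda = 100,
                                  p_asym = 0.5), "baseline")[1, ]
  expect_gt(mean(noisy >= bl_asym), mean(noisy >= bl_sym))
  expect_gte(mean(noisy >= bl_asym - 1e-6), 0.85)
  expect_lt(max(bl_asym - noisy), 2 * 0.02)
  expect_error(baseline_correct(make_sm(rbind(cst), wl), p_asym = 1.5),
               "p_asym")
})

test_that("apply_preprocess dispatches and round-trips its spec", {
  set.seed(18)
  sm <- make_sm(matrix(runif(5 * 30), 5, 30))
  expect_equal(apply_preprocess(sm, preprocess_spec("raw"))$X, sm$X)
  expect_equal(apply_preprocess(sm, preprocess_spec("msc"))$X, msc(sm)$X)
  spec <- preprocess_spec("sg_fd", window = 9, polyorder = 3)
  reparsed <- preprocess_spec_from_json(preprocess_spec_to_json(spec))
  expect_equal(apply_preprocess(sm, reparsed)$X,
               apply_preprocess(sm, spec)$X)
  bad <- preprocess_spec("raw"); bad$method <- "bogus"
  expect_error(apply_preprocess(sm, bad), "unknown")
})
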
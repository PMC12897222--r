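# Row-wise spectral preprocessing transforms. All operate on a
# spectra_matrix and return one, preserving grid/labels/ids.

as_X <- function(x) if (inherits(x, "spectra_matrix")) x$X else as.matrix(x)

rewrap <- function(x, X_new) {
  if (inherits(x, "spectra_matrix")) {
    spectra_matrix(X_new, x$grid, labels = x$labels, ids = x$ids)
  } else {
    X_new
  }
}

# Savitzky-Golay weights for every output position, including truncated
# one-sided edge windows (no reflection padding). Returns a B x B sparse-ish
# weight matrix applied as X %*% t(Wmat).
sg_weight_matrix <- function(B, window, polyorder, deriv = 0L) {
  half <- (window - 1L) %/% 2L
  Wmat <- matrix(0, B, B)
  # weight vectors depend only on the window's offset pattern; cache them
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(B)) {
    lo <- max(1L, i - half)
    hi <- min(B, i + half)
    offs <- (lo:hi) - i
    key <- paste(offs[1L], offs[length(offs)])
    w <- cache[[key]]
    if (is.null(w)) {
      V <- outer(offs, 0:polyorder, `^`)
      # row of (V'V)^-1 V' giving the deriv-th coefficient, times deriv!
      G <- solve(crossprod(V), t(V))
      w <- G[deriv + 1L, ] * factorial(deriv)
      cache[[key]] <- w
    }
    Wmat[i, lo:hi] <- w
  }
  Wmat
}

check_sg_params <- function(window, polyorder, B) {
  if (window %% 2L == 0L) stop("SG window must be odd, got ", window)
  if (window <= polyorder) stop("SG window must exceed polyorder")
  if (window > B) stop("SG window exceeds the number of bands")
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point of every spectrum by the value of a local
#' least-squares polynomial fit over a sliding window. At the spectrum edges
#' the window is truncated (one-sided fit, no reflection padding), so exact
#' polynomial reproduction holds at interior points.
#'
#' @param x a [spectra_matrix()] or numeric matrix (rows = spectra).
#' @param window odd window length (bands); default 11.
#' @param polyorder polynomial order, less than `window`; default 2.
#' @return The smoothed object, same class as `x`.
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 2L) {
  X <- as_X(x)
  check_sg_params(window, polyorder, ncol(X))
  Wm <- sg_weight_matrix(ncol(X), window, polyorder, deriv = 0L)
  rewrap(x, X %*% t(Wm))
}

#' Savitzky-Golay derivative
#'
#' First- or second-order derivative of each spectrum with respect to
#' wavelength (per nm): the analytic derivative of the local polynomial fit,
#' divided by the grid step raised to the derivative order. A non-uniform
#' grid triggers a warning and uses the mean step.
#'
#' @inheritParams sg_smooth
#' @param order derivative order, 1 or 2; `polyorder` must be >= `order`.
#' @param grid wavelength grid used for the step size when `x` is a bare
#'   matrix; ignored for a [spectra_matrix()].
#' @return The differentiated object, same class as `x`.
#' @export
sg_derivative <- function(x, window = 11L, polyorder = 2L, order = 1L,
                          grid = NULL) {
  if (!order %in% c(1L, 2L)) stop("derivative order must be 1 or 2")
  if (polyorder < order) stop("polyorder must be >= derivative order")
  X <- as_X(x)
  check_sg_params(window, polyorder, ncol(X))
  g <- if (inherits(x, "spectra_matrix")) x$grid else grid
  step <- if (is.null(g)) 1 else grid_step(g, warn = TRUE)
  Wm <- sg_weight_matrix(ncol(X), window, polyorder, deriv = order)
  rewrap(x, (X %*% t(Wm)) / step^order)
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum to a reference by ordinary least squares,
#' `x_i ~ a_i + b_i * ref`, and returns `(x_i - a_i) / b_i`. The reference
#' defaults to the column mean of `x` and is attached to the result
#' (attribute `reference`) so a training-set reference can be frozen and
#' reused on test spectra, avoiding leakage.
#'
#' @param x a [spectra_matrix()] or numeric matrix.
#' @param reference optional reference spectrum (length B); defaults to the
#'   column mean of `x`.
#' @return Same class as `x`, with attributes `reference` and `coef` (an
#'   N x 2 matrix of per-row `(a, b)`). Rows with `|b| < 1e-12` are left
#'   uncorrected with a warning.
#' @export
msc <- function(x, reference = NULL) {
  X <- as_X(x)
  if (is.null(reference)) {
    if (nrow(X) < 2L) stop("MSC needs >= 2 rows when no reference is given")
    reference <- colMeans(X)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) stop("reference length != number of bands")
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss < 1e-24) stop("reference spectrum is constant")
  b <- as.numeric(X %*% rc) / ss
  a <- rowMeans(X) - b * mean(reference)
  out <- X
  bad <- abs(b) < 1e-12
  if (any(bad)) {
    warning(sum(bad), " row(s) with |b| < 1e-12 left uncorrected")
  }
  ok <- !bad
  out[ok, ] <- (X[ok, , drop = FALSE] - a[ok]) / b[ok]
  res <- rewrap(x, out)
  attr(res, "reference") <- reference
  attr(res, "coef") <- cbind(a = a, b = b)
  res
}

#' Standard normal variate
#'
#' Centers each spectrum to mean zero and scales it to unit sample standard
#' deviation (denominator n - 1).
#'
#' @param x a [spectra_matrix()] or numeric matrix.
#' @return Same class as `x`. A zero-variance row is an error naming the row.
#' @export
snv <- function(x) {
  X <- as_X(x)
  mu <- rowMeans(X)
  s <- apply(X, 1L, sd)
  zero <- which(s < 1e-300)
  if (length(zero)) {
    stop("zero-variance row(s): ", paste(head(zero, 5L), collapse = ", "))
  }
  rewrap(x, (X - mu) / s)
}

#' Detrending
#'
#' Subtracts from each spectrum its least-squares polynomial fit against
#' wavelength, removing smooth baseline trends of the stated order.
#'
#' @param x a [spectra_matrix()] or numeric matrix.
#' @param polyorder polynomial order of the trend; default 2.
#' @param grid wavelength grid when `x` is a bare matrix.
#' @return Same class as `x`.
#' @export
detrend <- function(x, polyorder = 2L, grid = NULL) {
  X <- as_X(x)
  if (polyorder >= ncol(X)) stop("polyorder must be < number of bands")
  g <- if (inherits(x, "spectra_matrix")) as.numeric(x$grid) else
    if (is.null(grid)) seq_len(ncol(X)) else as.numeric(grid)
  u <- (g - mean(g)) / (max(g) - min(g))  # scaled for conditioning
  V <- outer(u, 0:polyorder, `^`)
  H <- V %*% solve(crossprod(V), t(V))
  rewrap(x, X - X %*% t(H))
}

#' Asymmetric least-squares baseline correction
#'
#' Estimates a smooth baseline under each spectrum by penalized least
#' squares with asymmetric weights (points above the baseline are
#' down-weighted by `p_asym`), then subtracts it. The smoothness penalty is
#' on second differences.
#'
#' @param x a [spectra_matrix()] or numeric matrix.
#' @param lambda smoothness penalty (larger = stiffer baseline).
#' @param p_asym asymmetry weight in (0, 1) for points above the baseline.
#' @param n_iter weight-reweighting iterations.
#' @param method `"als"` (default) or `"linear"` for a simple
#'   endpoint-to-endpoint linear baseline.
#' @return Same class as `x`, baseline-subtracted, with the fitted baselines
#'   in attribute `baseline`.
#' @export
baseline_correct <- function(x, lambda = 1e5, p_asym = 0.01, n_iter = 10L,
                             method = c("als", "linear")) {
  method <- match.arg(method)
  if (lambda <= 0) stop("lambda must be positive")
  if (p_asym <= 0 || p_asym >= 1) stop("p_asym must be in (0, 1)")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  X <- as_X(x)
  B <- ncol(X)
  bl <- matrix(0, nrow(X), B)
  if (method == "linear") {
    idx <- seq_len(B)
    for (i in seq_len(nrow(X))) {
      bl[i, ] <- X[i, 1L] + (X[i, B] - X[i, 1L]) * (idx - 1L) / (B - 1L)
    }
  } else {
    D <- Matrix::bandSparse(B - 2L, B, k = 0:2,
                            diagonals = list(rep(1, B - 2L),
                                             rep(-2, B - 2L),
                                             rep(1, B - 2L)))
    P <- lambda * Matrix::crossprod(D)
    for (i in seq_len(nrow(X))) {
      y <- X[i, ]
      w <- rep(1, B)
      z <- y
      for (it in seq_len(n_iter)) {
        Wd <- Matrix::Diagonal(x = w)
        z <- as.numeric(Matrix::solve(Wd + P, w * y))
        w_new <- ifelse(y > z, p_asym, 1 - p_asym)
        if (all(w_new == w)) break
        w <- w_new
      }
      bl[i, ] <- z
    }
  }
  res <- rewrap(x, X - bl)
  attr(res, "baseline") <- bl
  res
}

#' Preprocessing specification
#'
#' A serializable description of one preprocessing transform, dispatched by
#' [apply_preprocess()]. Methods: `raw` (identity), `sg`, `sg_fd`, `sg_sd`
#' (Savitzky-Golay smoothing / first / second derivative), `msc`, `snv`,
#' `detrend`, `baseline`.
#'
#' @param method one of the method names above.
#' @param window,polyorder Savitzky-Golay window and polynomial order.
#' @param detrend_order polynomial order for `detrend`.
#' @param lambda,p_asym,n_iter asymmetric least-squares baseline parameters.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("raw", "sg", "sg_fd", "sg_sd", "msc",
                                       "snv", "detrend", "baseline"),
                            window = 11L, polyorder = 2L, detrend_order = 2L,
                            lambda = 1e5, p_asym = 0.01, n_iter = 10L) {
  method <- match.arg(method)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and > polyorder")
  }
  structure(list(method = method, window = as.integer(window),
                 polyorder = as.integer(polyorder),
                 detrend_order = as.integer(detrend_order),
                 lambda = lambda, p_asym = p_asym,
                 n_iter = as.integer(n_iter)),
            class = "preprocess_spec")
}

#' Apply a preprocessing specification
#'
#' Dispatches to the transform named by a [preprocess_spec()]. For MSC the
#' fitted state (the training reference) is returned in attribute `state`;
#' pass it back via `state` to transform test spectra with the frozen
#' training reference.
#'
#' @param x a [spectra_matrix()] or numeric matrix.
#' @param spec a [preprocess_spec()].
#' @param state optional state from a previous call (MSC reference).
#' @return The transformed object, with attributes `spec` (the spec applied)
#'   and `state`.
#' @export
apply_preprocess <- function(x, spec, state = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  out <- switch(spec$method,
    raw = rewrap(x, as_X(x)),
    sg = sg_smooth(x, spec$window, spec$polyorder),
    sg_fd = sg_derivative(x, spec$window, spec$polyorder, order = 1L),
    sg_sd = sg_derivative(x, spec$window, max(spec$polyorder, 2L), order = 2L),
    msc = msc(x, reference = state$reference),
    snv = snv(x),
    detrend = detrend(x, spec$detrend_order),
    baseline = baseline_correct(x, spec$lambda, spec$p_asym, spec$n_iter),
    stop("unknown preprocessing method: ", spec$method))
  new_state <- if (spec$method == "msc") {
    list(reference = attr(out, "reference"))
  } else {
    NULL
  }
  attr(out, "spec") <- spec
  attr(out, "state") <- new_state
  out
}

#' Serialize and parse preprocessing specifications
#'
#' @param spec a [preprocess_spec()].
#' @return `preprocess_spec_to_json` returns a JSON string;
#'   `preprocess_spec_from_json` returns a [preprocess_spec()].
#' @export
preprocess_spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
}

#' @rdname preprocess_spec_to_json
#' @param json a JSON string produced by `preprocess_spec_to_json`.
#' @export
preprocess_spec_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  preprocess_spec(method = p$method, window = p$window,
                  polyorder = p$polyorder, detrend_order = p$detrend_order,
                  lambda = p$lambda, p_asym = p$p_asym, n_iter = p$n_iter)
}
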
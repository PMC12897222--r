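# Synthetic spectra and cube generator. Emulates the statistical structure
# of single-kernel NIR reflectance data from a stored-grain infestation
# study: a smooth base reflectance profile with water/starch absorption
# dips, class differences as smooth raised-cosine bumps localized to known
# discriminative windows, per-sample multiplicative/additive scatter, a
# small random polynomial baseline drift, and white noise.

#' Synthetic spectra configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 256 bands
#' over 850--1700 nm, 220 healthy and 369 infested kernels, class effects
#' localized to the 980--1100, 1200--1300 and 1400--1600 nm windows with
#' amplitude 0.02 reflectance units, lognormal multiplicative gain
#' (sd 0.05), additive offset (sd 0.01), degree-2 random baseline drift and
#' white noise (sd 0.005).
#'
#' @param n_healthy,n_infested class sizes.
#' @param grid a [wavelength_grid()].
#' @param effect_windows list of `c(low_nm, high_nm, amplitude)` triples;
#'   each contributes a raised-cosine reflectance bump to infested spectra.
#' @param gain_sd sd of `log(gain)` (gain is lognormal, median 1).
#' @param offset_sd sd of the per-sample additive offset.
#' @param baseline_sd length-3 sds of the random degree-2 baseline
#'   coefficients (constant, linear, quadratic on a \[-0.5, 0.5\] scale).
#' @param noise_sd per-band white-noise sd (reflectance units).
#' @param seed integer RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_healthy = 220L, n_infested = 369L,
                         grid = default_wavelength_grid(),
                         effect_windows = list(c(980, 1100, 0.02),
                                               c(1200, 1300, 0.02),
                                               c(1400, 1600, 0.02)),
                         gain_sd = 0.05, offset_sd = 0.01,
                         baseline_sd = c(0.01, 0.01, 0.01),
                         noise_sd = 0.005, seed = 1L) {
  if (n_healthy < 1L || n_infested < 1L) stop("class counts must be >= 1")
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  rng <- range(as.numeric(grid))
  for (w in effect_windows) {
    if (length(w) != 3L) stop("each effect window is c(low, high, amplitude)")
    if (w[1L] >= w[2L]) stop("effect window low must be < high")
    if (w[1L] < rng[1L] || w[2L] > rng[2L]) {
      stop("effect window ", w[1L], "-", w[2L], " nm outside the grid range")
    }
  }
  if (any(c(gain_sd, offset_sd, baseline_sd, noise_sd) < 0)) {
    stop("all sds must be >= 0")
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_infested = as.integer(n_infested), grid = grid,
                 effect_windows = effect_windows, gain_sd = gain_sd,
                 offset_sd = offset_sd, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# smooth wheat-like NIR reflectance: gentle upward slope with Gaussian
# absorption dips near the water (970, 1450 nm) and C-H (1200 nm) features
synth_base_profile <- function(wl) {
  0.45 + 0.10 * (wl - 850) / 850 -
    0.04 * exp(-((wl - 970) / 30)^2) -
    0.03 * exp(-((wl - 1200) / 35)^2) -
    0.10 * exp(-((wl - 1450) / 45)^2)
}

# class-difference profile: raised-cosine bump inside each window
synth_effect_profile <- function(wl, effect_windows) {
  eff <- numeric(length(wl))
  for (w in effect_windows) {
    inside <- wl > w[1L] & wl < w[2L]
    t_ <- (wl[inside] - w[1L]) / (w[2L] - w[1L])
    eff[inside] <- eff[inside] + w[3L] * 0.5 * (1 - cos(2 * pi * t_))
  }
  eff
}

#' Generate synthetic single-kernel spectra
#'
#' Each spectrum is
#' `gain * (base + label * effect + baseline) + offset + noise`, with the
#' components described in [synth_config()]. Healthy samples come first,
#' then infested; the run is reproducible bit-for-bit from the seed.
#'
#' @param cfg a [synth_config()].
#' @return A list with `spectra` (a labelled [spectra_matrix()]) and
#'   `truth`, which records `labels`, `informative_band_indices` (bands
#'   where the noiseless class-mean difference is nonzero), per-sample
#'   `gain` and `offset`, the `base_profile`, `effect_profile`, and the
#'   noiseless `class_means` (healthy, infested).
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  wl <- as.numeric(cfg$grid)
  B <- length(wl)
  n <- cfg$n_healthy + cfg$n_infested
  labels <- c(rep(0L, cfg$n_healthy), rep(1L, cfg$n_infested))
  base <- synth_base_profile(wl)
  eff <- synth_effect_profile(wl, cfg$effect_windows)
  old <- local_rng(cfg$seed)
  on.exit(restore_rng(old))
  gain <- rlnorm(n, 0, cfg$gain_sd)
  offset <- rnorm(n, 0, cfg$offset_sd)
  u <- (wl - mean(wl)) / (max(wl) - min(wl))
  bl_coef <- cbind(rnorm(n, 0, cfg$baseline_sd[1L]),
                   rnorm(n, 0, cfg$baseline_sd[2L]),
                   rnorm(n, 0, cfg$baseline_sd[3L]))
  baseline <- bl_coef %*% rbind(rep(1, B), u, u^2)
  clean <- outer(labels, eff) + rep(base, each = n) + baseline
  noise <- matrix(rnorm(n * B, 0, cfg$noise_sd), n, B)
  X <- gain * clean + offset + noise
  truth <- list(labels = labels,
                informative_band_indices = which(abs(eff) > 1e-12),
                gain = gain, offset = offset,
                base_profile = base, effect_profile = eff,
                class_means = rbind(healthy = base, infested = base + eff))
  list(spectra = spectra_matrix(X, cfg$grid, labels = labels),
       truth = truth)
}

#' Elliptical kernel layout
#'
#' Geometry of kernels on the imaging plate for [generate_cube()]: a list
#' of ellipses `(row, col, r_row, r_col)` in pixel units. The default lays
#' `n_kernels` out on a grid with fixed radii.
#'
#' @param n_kernels number of kernels.
#' @param image_dim `c(rows, cols)` of the image.
#' @param radii `c(r_row, r_col)` semi-axes in pixels.
#' @return A list of ellipse parameter vectors.
#' @export
ellipse_layout <- function(n_kernels, image_dim = c(96L, 96L),
                           radii = c(8, 5)) {
  per_row <- max(1L, floor(image_dim[2L] / (2 * radii[2L] + 8)))
  rows_needed <- ceiling(n_kernels / per_row)
  if (rows_needed * (2 * radii[1L] + 8) > image_dim[1L]) {
    stop("layout does not fit: enlarge image_dim or shrink radii")
  }
  lapply(seq_len(n_kernels) - 1L, function(i) {
    r <- (i %/% per_row) * (2 * radii[1L] + 8) + radii[1L] + 4
    cl <- (i %% per_row) * (2 * radii[2L] + 8) + radii[2L] + 4
    c(row = r, col = cl, r_row = radii[1L], r_col = radii[2L])
  })
}

#' Generate a synthetic raw hypercube with references
#'
#' Plants one reflectance spectrum per kernel (drawn via
#' [generate_spectra()]) into elliptical regions on a dark background, then
#' converts reflectance to raw counts with the given white/dark levels:
#' `raw = dark + reflectance * (white - dark) + pixel noise`. The matching
#' white and dark reference cubes, the ground-truth mask and the planted
#' per-kernel spectra are returned so the correction-segmentation-
#' extraction path can be validated end to end.
#'
#' @param cfg a [synth_config()]; must provide at least as many samples as
#'   kernels.
#' @param layout list of ellipses from [ellipse_layout()]; ellipses must be
#'   disjoint and inside the image.
#' @param image_dim image size `c(rows, cols)`.
#' @param white_level,dark_level reference count levels.
#' @param pixel_noise_sd sd of count noise added to the raw sample cube.
#' @param background_reflectance reflectance of the plate background.
#' @return A list with `raw`, `white`, `dark` ([hypercube()]s),
#'   `mask_truth` (a [kernel_mask()]), `spectra_truth` (a
#'   [spectra_matrix()] of the planted per-kernel spectra, kernels ordered
#'   as in the mask) and `labels` (per-kernel class codes).
#' @export
generate_cube <- function(cfg, layout = ellipse_layout(3L),
                          image_dim = c(96L, 96L), white_level = 1000,
                          dark_level = 100, pixel_noise_sd = 0,
                          background_reflectance = 0.02) {
  stopifnot(inherits(cfg, "synth_config"))
  K <- length(layout)
  gen <- generate_spectra(cfg)
  n <- nrow(gen$spectra$X)
  if (K > n) stop("layout has more kernels than the config has samples")
  old <- local_rng(cfg$seed + 1L)
  on.exit(restore_rng(old))
  rows_k <- sample.int(n, K)  # mix classes among kernels
  B <- length(cfg$grid)
  nr <- image_dim[1L]; nc <- image_dim[2L]
  labels_img <- matrix(0L, nr, nc)
  rr <- row(labels_img); cc <- col(labels_img)
  for (k in seq_len(K)) {
    e <- layout[[k]]
    inside <- ((rr - e["row"]) / e["r_row"])^2 +
      ((cc - e["col"]) / e["r_col"])^2 <= 1
    if (e["row"] - e["r_row"] < 1 || e["row"] + e["r_row"] > nr ||
        e["col"] - e["r_col"] < 1 || e["col"] + e["r_col"] > nc) {
      stop("ellipse ", k, " extends outside the image")
    }
    if (any(labels_img[inside] != 0L)) stop("ellipses ", k, " overlaps another")
    labels_img[inside] <- k
  }
  refl <- array(background_reflectance, dim = c(nr, nc, B))
  flat <- matrix(refl, nr * nc, B)
  for (k in seq_len(K)) {
    flat[labels_img == k, ] <- matrix(gen$spectra$X[rows_k[k], ],
                                      sum(labels_img == k), B, byrow = TRUE)
  }
  refl <- array(flat, dim = c(nr, nc, B))
  raw <- dark_level + refl * (white_level - dark_level)
  if (pixel_noise_sd > 0) {
    raw <- raw + array(rnorm(length(raw), 0, pixel_noise_sd), dim = dim(raw))
  }
  raw[raw < 0] <- 0
  white <- array(white_level, dim = c(nr, nc, B))
  dark <- array(dark_level, dim = c(nr, nc, B))
  list(raw = hypercube(raw, cfg$grid, "raw"),
       white = hypercube(white, cfg$grid, "raw"),
       dark = hypercube(dark, cfg$grid, "raw"),
       mask_truth = kernel_mask(labels_img),
       spectra_truth = spectra_matrix(gen$spectra$X[rows_k, , drop = FALSE],
                                      cfg$grid,
                                      labels = gen$truth$labels[rows_k],
                                      ids = as.character(seq_len(K))),
       labels = gen$truth$labels[rows_k])
}

#' Serialize and parse a synthetic configuration
#'
#' @param cfg a [synth_config()].
#' @param path optional file path (JSON or YAML chosen by extension).
#' @return `synth_config_to_json` returns the JSON string;
#'   `synth_config_from_list` rebuilds a [synth_config()] from a parsed
#'   list.
#' @export
synth_config_to_json <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  x <- unclass(cfg)
  x$grid <- as.numeric(x$grid)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname synth_config_to_json
#' @param x a list as produced by parsing the JSON/YAML serialization.
#' @export
synth_config_from_list <- function(x) {
  ew <- x$effect_windows
  if (is.matrix(ew)) ew <- lapply(seq_len(nrow(ew)), function(i) ew[i, ])
  if (is.data.frame(ew)) ew <- lapply(seq_len(nrow(ew)),
                                      function(i) as.numeric(ew[i, ]))
  synth_config(n_healthy = x$n_healthy, n_infested = x$n_infested,
               grid = wavelength_grid(as.numeric(unlist(x$grid))),
               effect_windows = lapply(ew, as.numeric),
               gain_sd = x$gain_sd, offset_sd = x$offset_sd,
               baseline_sd = as.numeric(unlist(x$baseline_sd)),
               noise_sd = x$noise_sd, seed = x$seed)
}
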
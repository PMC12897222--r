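#' Hyperspectral cube
#'
#' A 3-D image stack (rows x cols x bands) on a [wavelength_grid()], holding
#' either raw sensor counts or reflectance. The raw/reflectance distinction is
#' tracked in `kind` so that correction and segmentation can refuse
#' inappropriate inputs.
#'
#' @param data numeric 3-D array, rows x cols x bands.
#' @param grid a [wavelength_grid()] whose length matches `dim(data)[3]`.
#' @param kind `"raw"` (sensor counts, all values >= 0) or `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, grid, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (dim(data)[3L] != length(grid)) {
    stop("cube has ", dim(data)[3L], " bands but the grid has ",
         length(grid))
  }
  if (any(!is.finite(data))) stop("cube contains non-finite values")
  if (kind == "raw" && any(data < 0)) stop("raw counts must be >= 0")
  structure(list(data = data, grid = grid, kind = kind), class = "hypercube")
}

#' @exportS3Method base::print
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind=%s\n",
              d[1L], d[2L], d[3L], x$grid[1L], x$grid[length(x$grid)], x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Black-and-white reflectance correction
#'
#' Converts raw counts to reflectance using white and dark reference cubes:
#' `I = (I0 - B) / (W - B)` pixelwise, where `I0` is the raw sample cube, `B`
#' the dark (closed-shutter) reference and `W` the white (reference panel)
#' cube. The denominator is floored at `eps` times the white cube's dynamic
#' range to guard against dead pixels; the number of floored pixels is
#' attached as attribute `n_floored` and reported with a warning.
#'
#' @param raw,white,dark [hypercube()]s of identical shape and grid, all of
#'   kind `"raw"`.
#' @param eps relative denominator floor (fraction of the white dynamic
#'   range).
#' @param clip if `TRUE`, clamp the corrected reflectance to \[0, 1.2\];
#'   default leaves values unclipped.
#' @return A reflectance [hypercube()] with attribute `n_floored`.
#' @export
reflectance_correct <- function(raw, white, dark, eps = 1e-6, clip = FALSE) {
  for (cb in list(raw, white, dark)) {
    if (!inherits(cb, "hypercube")) stop("inputs must be hypercubes")
    if (cb$kind != "raw") stop("reflectance correction expects raw cubes")
  }
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data))) {
    stop("raw/white/dark cube shapes differ")
  }
  if (!isTRUE(all.equal(as.numeric(raw$grid), as.numeric(white$grid))) ||
      !isTRUE(all.equal(as.numeric(raw$grid), as.numeric(dark$grid)))) {
    stop("raw/white/dark wavelength grids differ")
  }
  denom <- white$data - dark$data
  floor_val <- eps * (max(white$data) - min(white$data))
  if (floor_val <= 0) floor_val <- eps
  n_floored <- sum(denom < floor_val)
  if (n_floored > 0L) {
    warning(n_floored, " pixel-band denominators floored at ",
            format(floor_val))
    denom[denom < floor_val] <- floor_val
  }
  out <- (raw$data - dark$data) / denom
  if (clip) out <- pmin(pmax(out, 0), 1.2)
  res <- hypercube(out, raw$grid, kind = "reflectance")
  attr(res, "n_floored") <- n_floored
  res
}

#' Otsu's threshold
#'
#' Histogram-based global threshold maximizing between-class variance, used to
#' binarize the grayscale kernel image before connected-component labelling.
#'
#' @param x numeric vector or matrix of grayscale values.
#' @param n_bins number of histogram bins.
#' @return The scalar threshold (bin edge); pixels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(rng[1L])
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  edges[k + 1L]
}

# 4-connected component labelling of a logical matrix; labels in scan order.
label_components_4 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(0)
  for (start in which(bw)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((px - 1L) %% nr) + 1L
      cl <- ((px - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) px - 1L,
                   if (r < nr) px + 1L,
                   if (cl > 1L) px - nr,
                   if (cl < nc) px + nr)) {
        if (bw[nb] && labels[nb] == 0L) {
          labels[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  labels
}

#' Kernel mask
#'
#' Integer label image for segmented kernels: 0 is background, 1..K identify
#' individual kernels.
#'
#' @param labels integer matrix of labels.
#' @param threshold optional grayscale threshold used to produce the mask.
#' @return An object of class `kernel_mask` with elements `labels`, `K`,
#'   `threshold`.
#' @export
kernel_mask <- function(labels, threshold = NA_real_) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  K <- max(labels, 0L)
  lab_set <- sort(unique(as.integer(labels)))
  if (!all(lab_set %in% 0:K) || !all(seq_len(K) %in% lab_set)) {
    stop("labels must be contiguous 0..K")
  }
  structure(list(labels = labels, K = K, threshold = threshold),
            class = "kernel_mask")
}

#' @exportS3Method base::print
print.kernel_mask <- function(x, ...) {
  cat(sprintf("<kernel_mask> %d x %d pixels, K=%d kernels\n",
              nrow(x$labels), ncol(x$labels), x$K))
  invisible(x)
}

#' Segment kernels from a reflectance cube
#'
#' Collapses the cube to a grayscale image (a single band or the band mean),
#' binarizes it with Otsu's threshold, labels 4-connected foreground
#' components, discards components below `min_area_px`, and renumbers the
#' survivors 1..K row-major by centroid so labelling is deterministic.
#' Touching kernels are not split; the workflow assumes kernels placed with
#' spacing on the imaging plate.
#'
#' @param cube a reflectance [hypercube()].
#' @param band single band index to use as the grayscale image, or `NULL`
#'   (default) for the mean over all bands.
#' @param min_area_px minimum component area in pixels.
#' @return A [kernel_mask()]; `K = 0` (with a warning) when no foreground
#'   survives.
#' @export
segment_kernels <- function(cube, band = NULL, min_area_px = 20L) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") stop("segmentation expects a reflectance cube")
  d <- dim(cube$data)
  gray <- if (is.null(band)) {
    rowMeans(matrix(cube$data, d[1L] * d[2L], d[3L]))
  } else {
    if (band < 1L || band > d[3L]) stop("band index out of range")
    as.numeric(cube$data[, , band])
  }
  gray <- matrix(gray, d[1L], d[2L])
  th <- otsu_threshold(gray)
  bw <- gray > th
  if (!any(bw)) {
    warning("empty foreground: no kernels found")
    return(kernel_mask(matrix(0L, d[1L], d[2L]), threshold = th))
  }
  lab <- label_components_4(bw)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) {
    warning("all components below min_area_px: no kernels found")
    return(kernel_mask(matrix(0L, d[1L], d[2L]), threshold = th))
  }
  # renumber by centroid, row-major (centroid row, then centroid column)
  cent <- t(vapply(keep, function(k) {
    idx <- which(lab == k)
    r <- ((idx - 1L) %% d[1L]) + 1L
    cl <- ((idx - 1L) %/% d[1L]) + 1L
    c(mean(r), mean(cl))
  }, numeric(2)))
  ord <- order(cent[, 1L], cent[, 2L])
  out <- matrix(0L, d[1L], d[2L])
  for (i in seq_along(ord)) out[lab == keep[ord[i]]] <- i
  kernel_mask(out, threshold = th)
}

#' Extract per-kernel mean spectra
#'
#' For each labelled kernel, averages the reflectance of all its pixels at
#' every band, producing one representative spectrum per kernel (the ROI mean
#' spectrum).
#'
#' @param cube a reflectance [hypercube()].
#' @param mask a [kernel_mask()] with the same spatial shape and `K >= 1`.
#' @return A [spectra_matrix()] with K rows; ids are the kernel label numbers.
#' @export
extract_mean_spectra <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "kernel_mask"))
  if (cube$kind != "reflectance") stop("extraction expects a reflectance cube")
  d <- dim(cube$data)
  if (!identical(dim(mask$labels), d[1:2])) {
    stop("mask shape does not match cube spatial shape")
  }
  if (mask$K < 1L) stop("mask has no kernels (K = 0)")
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  X <- t(vapply(seq_len(mask$K), function(k) {
    colMeans(flat[mask$labels == k, , drop = FALSE])
  }, numeric(d[3L])))
  spectra_matrix(X, cube$grid, ids = as.character(seq_len(mask$K)))
}

#' Write a kernel mask as CSV
#'
#' @param mask a [kernel_mask()].
#' @param path CSV path; cells hold integer labels.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "kernel_mask"))
  write.table(mask$labels, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
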
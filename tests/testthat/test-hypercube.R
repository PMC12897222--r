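test_that("ENVI round trip preserves values and wavelengths for all interleaves", {
  set.seed(11)
  g <- wavelength_grid(c(900, 1000.5, 1100))
  arr <- array(runif(5 * 7 * 3), dim = c(5, 7, 3))
  cube <- hypercube(arr, g, "raw")
  for (il in c("bsq", "bil", "bip")) {
    p <- tempfile(fileext = ".img")
    write_envi(cube, p, interleave = il)
    back <- read_envi(paste0(p, ".hdr"))
    expect_identical(dim(back$data), dim(arr))
    expect_equal(back$data, arr, tolerance = 0)
    expect_equal(as.numeric(back$grid), as.numeric(g))
  }
})

test_that("a hand-written BSQ byte payload is read back exactly", {
  # fixture written by an independent byte-level writer, not write_envi:
  # 2 lines x 2 samples x 3 bands of known integers, int16 little-endian
  vals <- array(c(1L, 2L, 3L, 4L,       # band 1 (row-major: r1c1 r1c2 r2c1 r2c2)
                  10L, 20L, 30L, 40L,   # band 2
                  7L, 0L, 5L, 100L),    # band 3
                dim = c(2, 2, 3))
  p <- tempfile(fileext = ".img")
  con <- file(p, "wb")
  # BSQ on disk: per band, sample fastest within each line
  for (b in 1:3) writeBin(as.integer(t(vals[, , b])), con, size = 2L,
                          endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 3",
               "data type = 2", "interleave = bsq", "byte order = 0",
               "wavelength = {900, 1000, 1100}"), paste0(p, ".hdr"))
  cube <- read_envi(paste0(p, ".hdr"))
  for (r in 1:2) for (cc in 1:2) for (b in 1:3) {
    expect_equal(as.double(cube$data[r, cc, b]),
                 as.double(vals[r, cc, b]))
  }
})

test_that("header/payload contradictions raise dimension and format errors", {
  p <- tempfile(fileext = ".img")
  con <- file(p, "wb")
  writeBin(as.double(1:12), con, size = 8L)  # 12 values
  close(con)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 4",
               "data type = 5", "interleave = bsq", "byte order = 0",
               "wavelength = {1, 2, 3}"), paste0(p, ".hdr"))
  expect_error(read_envi(paste0(p, ".hdr")), "wavelength")
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 4",
               "data type = 5", "interleave = bsq", "byte order = 0",
               "wavelength = {1, 2, 3, 4}"), paste0(p, ".hdr"))
  expect_error(read_envi(paste0(p, ".hdr")), "declares")
  writeLines(c("ENVI", "samples = 2", "lines = 2",
               "data type = 5", "interleave = bsq", "byte order = 0",
               "wavelength = {1, 2, 3}"), paste0(p, ".hdr"))
  expect_error(read_envi(paste0(p, ".hdr")), "bands")
})

test_that("reflectance correction follows (I0 - B) / (W - B)", {
  g <- wavelength_grid(c(1000, 1100))
  mk <- function(v) hypercube(array(v, dim = c(2, 2, 2)), g, "raw")
  white <- mk(120); dark <- mk(20)
  # I0 = W -> all ones; I0 = B -> all zeros; scalar case 60 -> 0.4
  expect_equal(reflectance_correct(mk(120), white, dark)$data,
               array(1, dim = c(2, 2, 2)))
  expect_equal(reflectance_correct(mk(20), white, dark)$data,
               array(0, dim = c(2, 2, 2)))
  expect_equal(reflectance_correct(mk(60), white, dark)$data,
               array(0.4, dim = c(2, 2, 2)))
})

test_that("reflectance correction is invariant to common positive scaling", {
  set.seed(5)
  g <- wavelength_grid(c(1000, 1100, 1200))
  raw <- array(runif(24, 50, 100), dim = c(2, 4, 3))
  white <- array(runif(24, 150, 200), dim = c(2, 4, 3))
  dark <- array(runif(24, 0, 10), dim = c(2, 4, 3))
  r1 <- reflectance_correct(hypercube(raw, g), hypercube(white, g),
                            hypercube(dark, g))
  r2 <- reflectance_correct(hypercube(raw * 7.3, g),
                            hypercube(white * 7.3, g),
                            hypercube(dark * 7.3, g))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("degenerate white = dark pixels are floored and counted", {
  g <- wavelength_grid(c(1000, 1100))
  raw <- hypercube(array(50, dim = c(2, 2, 2)), g)
  dark <- hypercube(array(20, dim = c(2, 2, 2)), g)
  wd <- array(120, dim = c(2, 2, 2))
  wd[1, 1, 1] <- 20  # W = B at one pixel-band
  white <- hypercube(wd, g)
  expect_warning(res <- reflectance_correct(raw, white, dark), "floored")
  expect_identical(attr(res, "n_floored"), 1L)
  expect_true(all(is.finite(res$data)))
})

test_that("shape and grid mismatches are dimension errors", {
  g <- wavelength_grid(c(1000, 1100))
  a <- hypercube(array(1, dim = c(2, 2, 2)), g)
  b <- hypercube(array(1, dim = c(2, 3, 2)), g)
  expect_error(reflectance_correct(a, b, a), "shapes")
  g2 <- wavelength_grid(c(1000, 1200))
  c2 <- hypercube(array(1, dim = c(2, 2, 2)), g2)
  expect_error(reflectance_correct(a, a, c2), "grids")
  expect_error(hypercube(array(1, dim = c(2, 2, 3)), g), "bands")
})

test_that("segmentation finds each planted ellipse with its exact area", {
  cfg <- synth_config(n_healthy = 3L, n_infested = 3L, seed = 4,
                      grid = wavelength_grid(seq(850, 1700, length.out = 8)))
  gc_ <- generate_cube(cfg, layout = ellipse_layout(3), pixel_noise_sd = 0)
  cube <- reflectance_correct(gc_$raw, gc_$white, gc_$dark)
  mask <- segment_kernels(cube, min_area_px = 10)
  expect_identical(mask$K, 3L)
  for (k in 1:3) {
    expect_identical(sum(mask$labels == k), sum(gc_$mask_truth$labels == k))
  }
  expect_identical(mask$labels, gc_$mask_truth$labels)
})

test_that("uniform dark cube yields K = 0 with a warning, not an error", {
  g <- wavelength_grid(c(1000, 1100))
  cube <- hypercube(array(0.02, dim = c(10, 10, 2)), g, "reflectance")
  expect_warning(mask <- segment_kernels(cube), "no kernels")
  expect_identical(mask$K, 0L)
})

test_that("components below min_area_px are discarded", {
  g <- wavelength_grid(c(1000, 1100))
  img <- array(0.02, dim = c(20, 20, 2))
  img[3:8, 3:8, ] <- 0.5       # 36 px
  img[15:16, 15:16, ] <- 0.5   # 4 px, below the cut
  cube <- hypercube(img, g, "reflectance")
  mask <- segment_kernels(cube, min_area_px = 10)
  expect_identical(mask$K, 1L)
  expect_identical(sum(mask$labels == 1L), 36L)
})

test_that("labelling is 4-connected: diagonal pixels are separate kernels", {
  g <- wavelength_grid(c(1000, 1100))
  img <- array(0.02, dim = c(12, 12, 2))
  img[3:5, 3:5, ] <- 0.5
  img[6:8, 6:8, ] <- 0.5  # touches the first block only at a corner
  cube <- hypercube(img, g, "reflectance")
  mask <- segment_kernels(cube, min_area_px = 2)
  expect_identical(mask$K, 2L)
})

test_that("mean-spectrum extraction equals the per-band arithmetic mean", {
  set.seed(21)
  g <- wavelength_grid(c(900, 1000, 1100, 1200))
  img <- array(0, dim = c(6, 6, 4))
  s <- c(0.2, 0.5, 0.3, 0.7)
  for (b in 1:4) img[2:3, 2:4, b] <- s[b]  # one ROI of identical spectra
  cube <- hypercube(img, g, "reflectance")
  lab <- matrix(0L, 6, 6); lab[2:3, 2:4] <- 1L
  sp <- extract_mean_spectra(cube, kernel_mask(lab))
  expect_equal(unname(sp$X[1, ]), s)

  # two pixels [0,1] and [1,0] average to [0.5, 0.5]
  g2 <- wavelength_grid(c(900, 1000))
  img2 <- array(0, dim = c(1, 2, 2))
  img2[1, 1, ] <- c(0, 1); img2[1, 2, ] <- c(1, 0)
  lab2 <- matrix(1L, 1, 2)
  sp2 <- extract_mean_spectra(hypercube(img2, g2, "reflectance"),
                              kernel_mask(lab2))
  expect_equal(unname(sp2$X[1, ]), c(0.5, 0.5))

  # random 5-pixel ROI vs brute-force average
  img3 <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  lab3 <- matrix(0L, 8, 8)
  pix <- cbind(c(1, 2, 5, 7, 8), c(3, 6, 1, 7, 2))
  lab3[pix] <- 1L
  sp3 <- extract_mean_spectra(hypercube(img3, g, "reflectance"),
                              kernel_mask(lab3))
  manual <- sapply(1:4, function(b) {
    mean(sapply(seq_len(nrow(pix)),
                function(i) img3[pix[i, 1], pix[i, 2], b]))
  })
  expect_equal(unname(sp3$X[1, ]), manual, tolerance = 1e-14)
  expect_error(extract_mean_spectra(hypercube(img3, g, "reflectance"),
                                    kernel_mask(matrix(0L, 8, 8))),
               "K = 0")
})

test_that("extraction commutes with per-band linear maps of the pixels", {
  set.seed(31)
  g <- wavelength_grid(c(900, 1000, 1100))
  img <- array(runif(5 * 5 * 3), dim = c(5, 5, 3))
  lab <- matrix(0L, 5, 5); lab[2:4, 2:3] <- 1L
  a <- c(2, -1, 0.5); b <- c(0.1, 0.3, -0.2)
  img2 <- img
  for (k in 1:3) img2[, , k] <- a[k] * img[, , k] + b[k]
  m1 <- extract_mean_spectra(hypercube(img, g, "reflectance"),
                             kernel_mask(lab))$X[1, ]
  m2 <- extract_mean_spectra(hypercube(img2, g, "reflectance"),
                             kernel_mask(lab))$X[1, ]
  expect_equal(unname(m2), unname(a * m1 + b), tolerance = 1e-12)
})
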
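#' Wavelength grid
#'
#' The band-center wavelengths (nm) shared by all spectra and hypercubes in a
#' pipeline. Wavelengths must be strictly increasing; the default grid mirrors
#' a push-broom NIR imaging spectrograph with 256 channels spanning
#' 850--1700 nm.
#'
#' @param wavelengths_nm numeric vector of strictly increasing band centers in
#'   nanometres, length at least 2.
#' @return An object of class `wavelength_grid`: a numeric vector of band
#'   centers with the class attribute set.
#' @examples
#' g <- default_wavelength_grid()
#' length(g)       # 256
#' range(g)        # 850 1700
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2L) {
    stop("wavelength grid needs at least 2 bands, got ", length(w))
  }
  if (anyNA(w) || any(!is.finite(w))) {
    stop("wavelength grid contains non-finite values")
  }
  if (any(diff(w) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(w, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param n_bands number of channels for the default grid.
#' @param from,to wavelength range (nm) for the default grid.
#' @export
default_wavelength_grid <- function(n_bands = 256L, from = 850, to = 1700) {
  wavelength_grid(seq(from, to, length.out = n_bands))
}

#' @exportS3Method base::print
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm (mean step %.2f nm)\n",
              length(x), x[1L], x[length(x)], mean(diff(x))))
  invisible(x)
}

# mean band spacing in nm; derivative scaling and non-uniform grid warnings
grid_step <- function(grid, warn = FALSE) {
  d <- diff(as.numeric(grid))
  if (warn && (max(d) - min(d)) > 1e-8 * mean(d)) {
    warning("non-uniform wavelength grid: using mean band spacing")
  }
  mean(d)
}
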
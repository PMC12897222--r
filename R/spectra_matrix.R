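#' Spectra matrix
#'
#' An N x B table of reflectance spectra on a common [wavelength_grid()], with
#' optional binary class labels (0 = healthy, 1 = infested) and sample
#' identifiers. This is the central container passed between preprocessing,
#' wavelength selection and classification.
#'
#' @param X numeric matrix, N samples by B bands; all entries finite.
#' @param grid a [wavelength_grid()] of length B.
#' @param labels optional integer vector in \{0, 1\}, length N.
#' @param ids optional character vector of sample identifiers, length N.
#' @return An object of class `spectra_matrix`: a list with elements `X`,
#'   `grid`, `labels`, `ids`.
#' @export
spectra_matrix <- function(X, grid, labels = NULL, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (ncol(X) != length(grid)) {
    stop("X has ", ncol(X), " columns but the grid has ", length(grid),
         " bands")
  }
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(X)) {
      stop("labels length ", length(labels), " != ", nrow(X), " rows")
    }
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels must be 0 (healthy) or 1 (infested)")
    }
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) stop("ids length != number of rows")
  colnames(X) <- formatC(as.numeric(grid), format = "f", digits = 1)
  rownames(X) <- ids
  structure(list(X = X, grid = grid, labels = labels, ids = ids),
            class = "spectra_matrix")
}

#' @exportS3Method base::print
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x$X), ncol(x$X), x$grid[1L], x$grid[length(x$grid)]))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d healthy (0), %d infested (1)\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  }
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$X)

#' Subset a spectra matrix
#'
#' @param x a [spectra_matrix()].
#' @param i row (sample) indices.
#' @param j column (band) indices.
#' @param ... unused.
#' @return A `spectra_matrix` restricted to the requested samples/bands.
#' @export
`[.spectra_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  spectra_matrix(x$X[i, j, drop = FALSE], wavelength_grid(as.numeric(x$grid)[j]),
                 labels = x$labels[i], ids = x$ids[i])
}

#' Read and write spectra matrices as CSV
#'
#' The on-disk schema is one row per sample: an `id` column, an optional
#' `label` column (0/1), then one column per wavelength whose header is the
#' band center in nm to one decimal.
#'
#' @param x a [spectra_matrix()].
#' @param path CSV file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_matrix()].
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_matrix"))
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df$label <- x$labels
  df <- cbind(df, as.data.frame(x$X, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("spectra CSV lacks an 'id' column: ", path)
  labels <- NULL
  meta <- "id"
  if ("label" %in% names(df)) {
    labels <- df$label
    meta <- c(meta, "label")
  }
  wl_cols <- setdiff(names(df), meta)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    stop("non-numeric wavelength headers in ", path, ": ",
         paste(wl_cols[is.na(wl)][1:3], collapse = ", "))
  }
  spectra_matrix(as.matrix(df[, wl_cols, drop = FALSE]), wavelength_grid(wl),
                 labels = labels, ids = df$id)
}
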
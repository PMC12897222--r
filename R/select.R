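# Common machinery for wavelength selection: the selection_result container,
# a spec-driven dispatcher, and SPA chaining of a second-stage selector onto
# a first-stage result.

#' Selection result
#'
#' The outcome of one wavelength-selection run: the ordered selected band
#' indices (1-based, ascending), their wavelengths, a per-iteration trace,
#' and the seed/parameters needed to reproduce the run bit-for-bit.
#'
#' @param method method tag (`cars`, `spa`, `uve`, `iriv`, `cars_spa`,
#'   `uve_spa`, `iriv_spa`).
#' @param selected integer vector of unique band indices in 1..B.
#' @param grid the [wavelength_grid()] the indices refer to.
#' @param trace list of per-iteration records.
#' @param seed RNG seed used.
#' @param params list of frozen parameters.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, selected, grid, trace = list(),
                             seed = NA_integer_, params = list()) {
  selected <- as.integer(selected)
  if (anyDuplicated(selected)) stop("selected indices must be unique")
  if (length(selected) &&
      (min(selected) < 1L || max(selected) > length(grid))) {
    stop("selected indices outside 1..B")
  }
  selected <- sort(selected)
  structure(list(method = method, selected = selected,
                 selected_nm = as.numeric(grid)[selected],
                 trace = trace, seed = seed, params = params),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d band(s)\n", x$method,
              length(x$selected)))
  if (length(x$selected)) {
    cat("  nm:", paste(formatC(x$selected_nm, format = "f", digits = 1),
                       collapse = " "), "\n")
  }
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param x a [selection_result()].
#' @param path optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to file.
#' @export
selection_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "selection_result"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Tabulate selection results
#'
#' Builds a summary table of one or more selection results — method, number
#' of selected bands, and the selected wavelengths in nm to one decimal —
#' the layout used for reporting joint wavelength-selection results.
#'
#' @param ... [selection_result()]s (optionally named).
#' @param path optional CSV export path.
#' @return A data.frame with columns `method`, `n_bands`, `bands_nm`.
#' @export
selection_table <- function(..., path = NULL) {
  res <- list(...)
  stopifnot(all(vapply(res, inherits, logical(1), "selection_result")))
  df <- do.call(rbind, lapply(res, function(r) {
    data.frame(method = r$method, n_bands = length(r$selected),
               bands_nm = paste(formatC(r$selected_nm, format = "f",
                                        digits = 1), collapse = " "),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Selector specification
#'
#' A serializable description of one wavelength-selection run, dispatched by
#' [run_selector()]. Chained methods (`cars_spa`, `uve_spa`, `iriv_spa`) run
#' the first-stage selector and then SPA restricted to its output.
#'
#' @param method one of `cars`, `spa`, `uve`, `iriv`, `cars_spa`, `uve_spa`,
#'   `iriv_spa`, or `none` (keep all bands).
#' @param ... method parameters overriding the defaults of the corresponding
#'   `select_*` function.
#' @return An object of class `selector_spec`.
#' @export
selector_spec <- function(method = c("none", "cars", "spa", "uve", "iriv",
                                     "cars_spa", "uve_spa", "iriv_spa"),
                          ...) {
  method <- match.arg(method)
  structure(list(method = method, params = list(...)),
            class = "selector_spec")
}

#' Run a selector specification
#'
#' @param X numeric matrix or [spectra_matrix()] (training rows only).
#' @param y numeric class codes (0/1).
#' @param spec a [selector_spec()].
#' @param grid wavelength grid when `X` is a bare matrix.
#' @param seed RNG seed forwarded to stochastic selectors.
#' @return A [selection_result()].
#' @export
run_selector <- function(X, y, spec, grid = NULL, seed = 1L) {
  stopifnot(inherits(spec, "selector_spec"))
  if (inherits(X, "spectra_matrix")) {
    grid <- X$grid
    X <- X$X
  }
  if (is.null(grid)) grid <- wavelength_grid(seq_len(ncol(X)))
  p <- spec$params
  call_sel <- function(fn, base) {
    do.call(fn, c(list(X = X, y = y, grid = grid),
                  modifyList(base, p)))
  }
  switch(spec$method,
    none = selection_result("none", seq_len(ncol(X)), grid, seed = seed),
    cars = call_sel(select_cars, list(seed = seed)),
    spa = call_sel(select_spa, list()),
    uve = call_sel(select_uve, list(seed = seed)),
    iriv = call_sel(select_iriv, list(seed = seed)),
    cars_spa = chain_spa(call_sel(select_cars, list(seed = seed)),
                         X, y, grid, p),
    uve_spa = chain_spa(call_sel(select_uve, list(seed = seed)),
                        X, y, grid, p),
    iriv_spa = chain_spa(call_sel(select_iriv, list(seed = seed)),
                         X, y, grid, p),
    stop("unknown selector method: ", spec$method))
}

chain_spa <- function(first, X, y, grid, params) {
  spa_params <- params[names(params) %in%
                         c("n_min", "n_max", "plan", "max_pc", "use_mlr")]
  second <- do.call(select_chain,
                    c(list(first = first, X = X, y = y, grid = grid,
                           selector = "spa"), spa_params))
  second
}

#' Chain a second-stage selector onto a first-stage result
#'
#' Runs a second selector on the column subset retained by `first` and maps
#' the returned indices back to the original grid. Used to compress CARS,
#' UVE or IRIV selections with SPA.
#'
#' @param first a non-empty [selection_result()].
#' @param X,y the same training data the first stage saw.
#' @param grid wavelength grid when `X` is a bare matrix.
#' @param selector `"spa"` or `"identity"` (returns the first stage
#'   unchanged).
#' @param ... parameters for the second-stage selector.
#' @return A [selection_result()] whose `selected` is a subset of
#'   `first$selected` and whose method tag reflects the combination.
#' @export
select_chain <- function(first, X, y, grid = NULL, selector = "spa", ...) {
  stopifnot(inherits(first, "selection_result"))
  if (length(first$selected) == 0L) {
    stop("cannot chain onto an empty first-stage selection")
  }
  if (inherits(X, "spectra_matrix")) {
    grid <- X$grid
    X <- X$X
  }
  if (is.null(grid)) grid <- wavelength_grid(seq_len(ncol(X)))
  if (selector == "identity") {
    out <- first
    return(out)
  }
  if (selector != "spa") stop("unsupported chain selector: ", selector)
  sub <- first$selected
  sub_grid <- wavelength_grid(as.numeric(grid)[sub])
  second <- select_spa(X[, sub, drop = FALSE], y, grid = sub_grid, ...)
  selection_result(paste0(first$method, "_spa"),
                   selected = sub[second$selected], grid = grid,
                   trace = list(first = first$trace, second = second$trace),
                   seed = first$seed,
                   params = list(first = first$params,
                                 second = second$params))
}
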
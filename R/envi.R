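# ENVI raster I/O: ASCII header (.hdr) + flat binary payload.
# Supported interleaves: bsq, bil, bip; data types 1 (uint8), 2 (int16),
# 4 (float32), 5 (float64), 12 (uint16). No installed package reads this
# format, so the parser lives here.

envi_dtype <- function(code) {
  switch(as.character(code),
         "1"  = list(what = "integer", size = 1L, signed = FALSE),
         "2"  = list(what = "integer", size = 2L, signed = TRUE),
         "4"  = list(what = "double",  size = 4L, signed = TRUE),
         "5"  = list(what = "double",  size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported ENVI data type: ", code))
}

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1L])) {
    stop("not an ENVI header (missing ENVI magic line): ", header_path)
  }
  body <- paste(txt[-1L], collapse = "\n")
  fields <- list()
  # match "key = value" where value may be a braced multi-line list
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1L] == -1L) stop("no fields found in ENVI header: ", header_path)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    kv <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- trimws(substr(kv, 1L, eq - 1L))
    val <- trimws(substr(kv, eq + 1L, nchar(kv)))
    fields[[tolower(key)]] <- val
  }
  fields
}

envi_field_num <- function(fields, name, path) {
  if (is.null(fields[[name]])) {
    stop("ENVI header is missing required field '", name, "': ", path)
  }
  v <- suppressWarnings(as.numeric(fields[[name]]))
  if (is.na(v)) stop("ENVI header field '", name, "' is not numeric: ", path)
  v
}

#' Read an ENVI hyperspectral cube
#'
#' Parses an ENVI ASCII header and its companion binary payload and returns a
#' [hypercube()] laid out rows x cols x bands regardless of the on-disk
#' interleave (`bsq`, `bil` or `bip`). The wavelength list in the header
#' becomes the cube's [wavelength_grid()].
#'
#' @param header_path path to the `.hdr` file. The binary payload is looked
#'   up at the path with the `.hdr` extension stripped (or `.img`/`.dat`
#'   appended).
#' @param kind `"raw"` or `"reflectance"` for the returned cube.
#' @return A [hypercube()].
#' @export
read_envi <- function(header_path, kind = "raw") {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  fields <- parse_envi_header(header_path)
  samples <- as.integer(envi_field_num(fields, "samples", header_path))
  lines_n <- as.integer(envi_field_num(fields, "lines", header_path))
  bands <- as.integer(envi_field_num(fields, "bands", header_path))
  dtype <- envi_dtype(as.integer(envi_field_num(fields, "data type",
                                                header_path)))
  interleave <- tolower(trimws(fields[["interleave"]] %||% "bsq"))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported interleave '", interleave, "' in ", header_path)
  }
  byte_order <- as.integer(fields[["byte order"]] %||% "0")
  endian <- if (byte_order == 0L) "little" else "big"
  if (is.null(fields[["wavelength"]])) {
    stop("ENVI header is missing required field 'wavelength': ", header_path)
  }
  wl_txt <- gsub("[{}]", "", fields[["wavelength"]])
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != bands) {
    stop("header declares ", bands, " bands but lists ", length(wl),
         " wavelengths: ", header_path)
  }
  bin_path <- envi_binary_path(header_path)
  n_expect <- samples * lines_n * bands
  n_have <- file.info(bin_path)$size / dtype$size
  if (n_have != n_expect) {
    stop("payload holds ", n_have, " values but header declares ", n_expect,
         " (", lines_n, " lines x ", samples, " samples x ", bands,
         " bands): ", bin_path)
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, dtype$what, n = n_expect, size = dtype$size,
               signed = dtype$signed, endian = endian)
  arr <- switch(interleave,
    # bsq: sample fastest, then line, then band
    bsq = aperm(array(v, dim = c(samples, lines_n, bands)), c(2L, 1L, 3L)),
    # bil: sample fastest, then band, then line
    bil = aperm(array(v, dim = c(samples, bands, lines_n)), c(3L, 1L, 2L)),
    # bip: band fastest, then sample, then line
    bip = aperm(array(v, dim = c(bands, samples, lines_n)), c(3L, 2L, 1L)))
  hypercube(arr, wavelength_grid(wl), kind = kind)
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (cand in c(base, paste0(base, ".img"), paste0(base, ".dat"))) {
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  }
  stop("companion binary not found for header: ", header_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hypercube as an ENVI raster
#'
#' @param cube a [hypercube()].
#' @param path payload path; the header is written next to it as
#'   `<path>.hdr`.
#' @param interleave on-disk layout: `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data-type code (default 5, float64, which
#'   round-trips exactly).
#' @return The header path, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  dtype <- envi_dtype(data_type)
  d <- dim(cube$data)
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2L, 1L, 3L)),
    bil = aperm(cube$data, c(2L, 3L, 1L)),
    bip = aperm(cube$data, c(3L, 2L, 1L)))
  v <- as.vector(arr)
  con <- file(path, "wb")
  writeBin(if (dtype$what == "integer") as.integer(round(v)) else as.double(v),
           con, size = dtype$size, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {grainspec export}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = Nanometers"),
    paste0("wavelength = {", paste(format(as.numeric(cube$grid), trim = TRUE),
                                   collapse = ", "), "}"))
  hdr_path <- paste0(path, ".hdr")
  writeLines(hdr, hdr_path)
  invisible(hdr_path)
}
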
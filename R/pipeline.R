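# Configuration-driven experiment grid: preprocessing x selector x
# classifier combinations over one dataset, with train-only fitting of
# preprocessing statistics and selectors (no test-set leakage) and a config
# hash embedded in every output.

#' Experiment configuration
#'
#' Describes one experiment grid: a data source (a [synth_config()], a
#' spectra CSV path, or an ENVI cube set), the lists of preprocessing,
#' selector and classifier specifications, the split ratio and the seed.
#'
#' @param data a [synth_config()], or a list like
#'   `list(type = "csv", path = ...)` or `list(type = "envi", raw = ,
#'   white = , dark = , labels = )` (labels optional CSV of id,label).
#' @param preprocess list of [preprocess_spec()]s.
#' @param selectors list of [selector_spec()]s.
#' @param classifiers list of [classifier_spec()]s.
#' @param split_ratio Kennard-Stone training fraction.
#' @param seed master seed for selectors and classifiers.
#' @param outdir optional directory for artifacts (selection JSON,
#'   confusion CSV).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(data, preprocess = list(preprocess_spec("raw")),
                              selectors = list(selector_spec("none")),
                              classifiers = list(classifier_spec("svm_rbf")),
                              split_ratio = 0.7, seed = 1L, outdir = NULL) {
  if (length(preprocess) == 0L || length(selectors) == 0L ||
      length(classifiers) == 0L) {
    stop("each grid axis needs at least one entry")
  }
  stopifnot(all(vapply(preprocess, inherits, logical(1), "preprocess_spec")),
            all(vapply(selectors, inherits, logical(1), "selector_spec")),
            all(vapply(classifiers, inherits, logical(1), "classifier_spec")))
  structure(list(data = data, preprocess = preprocess, selectors = selectors,
                 classifiers = classifiers, split_ratio = split_ratio,
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' Hash an experiment configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every results table
#' and artifact so outputs from different configurations are never merged.
#'
#' @param cfg an [experiment_config()] (or any serializable list).
#' @return A character MD5 digest.
#' @export
config_hash <- function(cfg) {
  x <- rapply(unclass(cfg), function(v) {
    if (inherits(v, "wavelength_grid")) as.numeric(v) else v
  }, how = "replace")
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

load_experiment_data <- function(data) {
  if (inherits(data, "synth_config")) {
    return(generate_spectra(data)$spectra)
  }
  if (is.list(data) && identical(data$type, "csv")) {
    return(read_spectra_csv(data$path))
  }
  if (is.list(data) && identical(data$type, "envi")) {
    raw <- read_envi(data$raw)
    white <- read_envi(data$white)
    dark <- read_envi(data$dark)
    cube <- reflectance_correct(raw, white, dark)
    mask <- segment_kernels(cube)
    sp <- extract_mean_spectra(cube, mask)
    if (!is.null(data$labels)) {
      lab <- read.csv(data$labels, stringsAsFactors = FALSE)
      sp$labels <- as.integer(lab$label[match(sp$ids, as.character(lab$id))])
    }
    return(sp)
  }
  stop("unrecognized data source")
}

#' Run an experiment grid
#'
#' For every preprocessing x selector x classifier combination: split the
#' samples with Kennard-Stone (on the raw spectra, so preprocessing
#' statistics can be fitted on training rows only), fit the preprocessing
#' on the training rows and transform both partitions with the frozen
#' state, run the selector on the training rows, subset both partitions to
#' the selected bands, tune/train the classifier, and evaluate on the test
#' rows. A failed combination is recorded with `failed = TRUE` and the run
#' continues.
#'
#' @param cfg an [experiment_config()].
#' @return A data.frame with one row per combination: `preprocess`,
#'   `selector`, `classifier`, `n_bands`, `train_acc`, `test_acc`, `f1`,
#'   `kappa`, `failed`, plus the config hash in attribute `config_hash`
#'   (and column `hash`). Artifacts are written under `cfg$outdir` when
#'   set.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  hash <- config_hash(cfg)
  sp <- load_experiment_data(cfg$data)
  if (is.null(sp$labels)) stop("experiment data has no class labels")
  split <- kennard_stone_split(sp, ratio = cfg$split_ratio)
  tr <- split$train_ids
  te <- split$test_ids
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE)
  }
  rows <- list()
  for (ip in seq_along(cfg$preprocess)) {
    psp <- cfg$preprocess[[ip]]
    prep_tr <- apply_preprocess(sp[tr, ], psp)
    prep_te <- apply_preprocess(sp[te, ], psp,
                                state = attr(prep_tr, "state"))
    for (is_ in seq_along(cfg$selectors)) {
      ssp <- cfg$selectors[[is_]]
      for (ic in seq_along(cfg$classifiers)) {
        csp <- cfg$classifiers[[ic]]
        tag <- paste(psp$method, ssp$method, csp$kind, sep = "-")
        row <- tryCatch({
          sel <- run_selector(prep_tr$X, sp$labels[tr], ssp,
                              grid = sp$grid, seed = cfg$seed)
          bands <- if (length(sel$selected)) sel$selected else
            stop("selector returned no bands")
          model <- tune_and_train(prep_tr$X[, bands, drop = FALSE],
                                  sp$labels[tr], csp)
          rep_tr <- evaluate_model(model, prep_tr$X[, bands, drop = FALSE],
                                   sp$labels[tr])
          rep_te <- evaluate_model(model, prep_te$X[, bands, drop = FALSE],
                                   sp$labels[te])
          if (!is.null(cfg$outdir)) {
            selection_to_json(sel, file.path(cfg$outdir,
                                             paste0(tag, "-selection.json")))
            confusion_table(rep_te, file.path(cfg$outdir,
                                              paste0(tag, "-confusion.csv")))
          }
          data.frame(preprocess = psp$method, selector = ssp$method,
                     classifier = csp$kind, n_bands = length(bands),
                     train_acc = rep_tr$acc, test_acc = rep_te$acc,
                     f1 = rep_te$f1, kappa = rep_te$kappa, failed = FALSE,
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          warning("combination ", tag, " failed: ", conditionMessage(e))
          data.frame(preprocess = psp$method, selector = ssp$method,
                     classifier = csp$kind, n_bands = NA_integer_,
                     train_acc = NA_real_, test_acc = NA_real_,
                     f1 = NA_real_, kappa = NA_real_, failed = TRUE,
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, rows)
  res$hash <- hash
  attr(res, "config_hash") <- hash
  if (!is.null(cfg$outdir)) {
    write.csv(res, file.path(cfg$outdir, "results.csv"), row.names = FALSE)
  }
  res
}

#' Summarize experiment results
#'
#' Merges one or more results tables (refusing tables with differing config
#' hashes) and reports the best combination by test accuracy.
#'
#' @param ... results data.frames from [run_experiment()], or paths to
#'   their CSV exports.
#' @return A list with `results` (the merged table) and `best` (its
#'   highest-test-accuracy row).
#' @export
summarize_results <- function(...) {
  tabs <- lapply(list(...), function(x) {
    if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  })
  hashes <- unique(unlist(lapply(tabs, function(t) unique(t$hash))))
  if (length(hashes) > 1L) {
    stop("refusing to merge results with different config hashes: ",
         paste(hashes, collapse = ", "))
  }
  res <- do.call(rbind, tabs)
  ok <- res[!res$failed & !is.na(res$test_acc), , drop = FALSE]
  best <- if (nrow(ok)) ok[which.max(ok$test_acc), , drop = FALSE] else NULL
  list(results = res, best = best)
}
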
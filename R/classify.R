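# Kennard-Stone partitioning, the four classifiers with fixed/tuned
# hyperparameters, and confusion-matrix evaluation. The classifiers
# themselves come from established libraries (e1071, rpart, class,
# randomForest); this module owns the hyperparameters, the tuning rule and
# determinism under seeds.

#' Kennard-Stone sample partitioning
#'
#' Deterministic maximin split: starting from the pair of samples with the
#' greatest Euclidean distance, samples are added one at a time by
#' maximizing their minimum distance to the already-selected set, until the
#' training set holds `round(ratio * N)` samples. Distance ties are broken
#' by the lowest row index.
#'
#' @param X numeric matrix or [spectra_matrix()].
#' @param ratio training fraction in (0, 1).
#' @return An object of class `split_plan`: list with integer `train_ids`,
#'   `test_ids` (row indices) and `ratio`.
#' @export
kennard_stone_split <- function(X, ratio = 0.7) {
  if (inherits(X, "spectra_matrix")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n_train <- round(ratio * n)
  n_train <- max(2L, min(n - 1L, n_train))
  D <- unname(as.matrix(stats::dist(X)))
  dimnames(D) <- NULL
  # initial pair: global maximum distance, lowest indices on ties
  mx <- max(D)
  hit <- which(D == mx, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  sel <- sort(unname(c(hit[1L, 1L], hit[1L, 2L])))
  min_d <- pmin(D[, sel[1L]], D[, sel[2L]])
  min_d[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(min_d)  # which.max takes the first (lowest) index on ties
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, D[, nxt])
    min_d[nxt] <- -Inf
  }
  sel <- sort(unname(sel))
  structure(list(train_ids = sel, test_ids = setdiff(seq_len(n), sel),
                 ratio = ratio),
            class = "split_plan")
}

#' @exportS3Method base::print
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / test %d (ratio %.2f)\n",
              length(x$train_ids), length(x$test_ids), x$ratio))
  invisible(x)
}

#' Classifier specification
#'
#' Hyperparameters for the four classifier families. Defaults follow
#' standard practice for single-kernel NIR discrimination: an RBF-kernel
#' SVM with cost 2.5 and automatic kernel scale (gamma = 1/B), a
#' Gini-criterion decision tree capped at 20 splits, a Minkowski (p = 2)
#' equal-weight KNN with K tuned over \{3, 5, 7, 9, 11, 15, 20\}, and a
#' 200-tree random forest with minimum leaf size 5.
#'
#' @param kind `svm_rbf`, `dt`, `knn` or `rf`.
#' @param cost SVM penalty parameter.
#' @param cost_grid SVM tuning grid (used when `tune = TRUE`), centered on
#'   `cost`.
#' @param max_splits decision-tree split cap.
#' @param k_grid KNN neighbour grid.
#' @param n_trees,min_leaf random-forest size and minimum node size.
#' @param tune run 5-fold grid-search tuning on the training set (SVM cost,
#'   KNN K). DT and RF train at the fixed parameters.
#' @param n_folds tuning CV folds.
#' @param seed RNG seed for tuning folds and stochastic learners.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "dt", "knn", "rf"),
                            cost = 2.5, cost_grid = cost * 2^(-2:2),
                            max_splits = 20L,
                            k_grid = c(3L, 5L, 7L, 9L, 11L, 15L, 20L),
                            n_trees = 200L, min_leaf = 5L,
                            tune = TRUE, n_folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  if (tune && kind == "svm_rbf" && length(cost_grid) == 0L) {
    stop("empty tuning grid")
  }
  if (tune && kind == "knn" && length(k_grid) == 0L) stop("empty K grid")
  structure(list(kind = kind, cost = cost, cost_grid = cost_grid,
                 max_splits = as.integer(max_splits),
                 k_grid = as.integer(k_grid),
                 n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf), tune = tune,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

# automatic RBF kernel scale: median pairwise Euclidean distance on (a
# subsample of) the training rows, giving gamma = 1/(2 * scale^2)
auto_gamma <- function(X, max_rows = 200L) {
  if (nrow(X) > max_rows) {
    X <- X[round(seq(1L, nrow(X), length.out = max_rows)), , drop = FALSE]
  }
  s <- median(stats::dist(X))
  if (!is.finite(s) || s <= 0) s <- 1
  1 / (2 * s^2)
}

fit_one <- function(kind, spec, X, y) {
  yf <- factor(y, levels = c(0L, 1L))
  switch(kind,
    svm_rbf = e1071::svm(X, yf, kernel = "radial", cost = spec$.cost_now,
                         gamma = auto_gamma(X), scale = FALSE),
    dt = fit_dt(X, yf, spec$max_splits),
    knn = list(X = X, y = yf, k = spec$.k_now),  # lazy learner
    rf = randomForest::randomForest(X, yf, ntree = spec$n_trees,
                                    nodesize = spec$min_leaf))
}

# rpart with the Gini criterion, grown deep then pruned back to the largest
# subtree with at most max_splits splits
fit_dt <- function(X, yf, max_splits) {
  df <- data.frame(.y = yf, X, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 5,
                                                     maxsurrogate = 0))
  ct <- fit$cptable
  ok <- ct[, "nsplit"] <= max_splits
  cp_keep <- ct[max(which(ok)), "CP"]
  rpart::prune(fit, cp = cp_keep + 1e-12)
}

predict_one <- function(kind, model, X) {
  switch(kind,
    svm_rbf = predict(model, X),
    dt = {
      df <- data.frame(X, check.names = FALSE)
      factor(predict(model, df, type = "class"), levels = c(0L, 1L))
    },
    knn = class::knn(model$X, X, model$y, k = model$k),
    rf = predict(model, X))
}

#' Tune and train a classifier
#'
#' SVM: grid search over the cost grid with 5-fold CV on the training set;
#' KNN: K chosen from the grid by maximum CV accuracy, Cohen's kappa as the
#' tie-break, then the smaller K. DT and RF train directly at their fixed
#' parameters. All CV folds and stochastic learners are seeded, so the same
#' data and spec yield an identical tuning trace.
#'
#' @param X_train numeric matrix or [spectra_matrix()] of training spectra.
#' @param y_train integer class codes (0/1), both classes present.
#' @param spec a [classifier_spec()].
#' @return An object of class `trained_classifier` with the fitted model,
#'   the chosen hyperparameters and the tuning trace.
#' @export
tune_and_train <- function(X_train, y_train, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (inherits(X_train, "spectra_matrix")) X_train <- X_train$X
  X_train <- as.matrix(X_train)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L) {
    stop("training labels contain a single class")
  }
  old <- local_rng(spec$seed)
  on.exit(restore_rng(old))
  tuning <- NULL
  chosen <- list()
  grid_vals <- if (spec$tune && spec$kind == "svm_rbf") {
    sort(spec$cost_grid)
  } else if (spec$tune && spec$kind == "knn") {
    sort(spec$k_grid)
  } else {
    NULL
  }
  if (!is.null(grid_vals)) {
    folds <- plan_folds(cv_plan(spec$n_folds, spec$seed), length(y_train),
                        y_train)
    scores <- t(vapply(grid_vals, function(g) {
      pred <- integer(length(y_train))
      for (f in sort(unique(folds))) {
        te <- folds == f
        sp <- spec
        if (spec$kind == "svm_rbf") sp$.cost_now <- g else sp$.k_now <- g
        m <- fit_one(spec$kind, sp, X_train[!te, , drop = FALSE],
                     y_train[!te])
        pred[te] <- as.integer(as.character(
          predict_one(spec$kind, m, X_train[te, , drop = FALSE])))
      }
      c(acc = mean(pred == y_train),
        kappa = cohen_kappa(table(factor(y_train, levels = 0:1),
                                  factor(pred, levels = 0:1))))
    }, numeric(2)))
    tuning <- data.frame(value = grid_vals, acc = scores[, "acc"],
                         kappa = scores[, "kappa"])
    # max accuracy, kappa tie-break, then the smaller parameter value
    best <- order(-tuning$acc, -tuning$kappa, tuning$value)[1L]
    chosen <- list(value = grid_vals[best])
  }
  sp <- spec
  sp$.cost_now <- if (spec$kind == "svm_rbf") {
    if (length(chosen)) chosen$value else spec$cost
  } else {
    spec$cost
  }
  sp$.k_now <- if (spec$kind == "knn") {
    if (length(chosen)) chosen$value else spec$k_grid[1L]
  } else {
    NA_integer_
  }
  model <- fit_one(spec$kind, sp, X_train, y_train)
  structure(list(kind = spec$kind, model = model, spec = spec,
                 chosen = chosen, tuning = tuning),
            class = "trained_classifier")
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_matrix")) newdata <- newdata$X
  old <- local_rng(object$spec$seed)  # KNN vote ties are randomized
  on.exit(restore_rng(old))
  as.integer(as.character(predict_one(object$kind, object$model,
                                      as.matrix(newdata))))
}

#' @exportS3Method base::print
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %s%s\n", x$kind,
              if (length(x$chosen)) paste0(" (tuned value ",
                                           x$chosen$value, ")") else ""))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` computed from the confusion-matrix marginals.
#'
#' @param cm a square contingency table / matrix (true x predicted).
#' @return Kappa in \[-1, 1\]; 1 when the marginals predict perfect
#'   agreement already (degenerate `p_e = 1`).
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Evaluate a classifier on a test set
#'
#' Builds the 2x2 confusion matrix with infested (label 1) as the positive
#' class and computes accuracy, precision, recall, F1 (for the positive
#' class) and Cohen's kappa.
#'
#' @param model a [tune_and_train()] result (or anything with a `predict`
#'   method returning 0/1).
#' @param X_test numeric matrix or [spectra_matrix()].
#' @param y_test integer class codes (0/1), non-empty.
#' @return An object of class `eval_report`: list with `confusion` (named
#'   counts TP, FN, FP, TN), `acc`, `precision`, `recall`, `f1`, `kappa`.
#'   Rates are proportions in \[0, 1\].
#' @export
evaluate_model <- function(model, X_test, y_test) {
  if (inherits(X_test, "spectra_matrix")) X_test <- X_test$X
  y_test <- as.integer(y_test)
  if (length(y_test) == 0L) stop("empty test set")
  pred <- predict(model, X_test)
  eval_report_from_counts(
    tp = sum(pred == 1L & y_test == 1L),
    fn = sum(pred == 0L & y_test == 1L),
    fp = sum(pred == 1L & y_test == 0L),
    tn = sum(pred == 0L & y_test == 0L))
}

#' Build an evaluation report from confusion counts
#'
#' @param tp,fn,fp,tn confusion counts with infested = positive.
#' @return An `eval_report`; see [evaluate_model()].
#' @export
eval_report_from_counts <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  cm <- matrix(c(tp, fn, fp, tn), 2L, 2L, byrow = TRUE,
               dimnames = list(true = c("1", "0"), pred = c("1", "0")))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
                 acc = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1, kappa = cohen_kappa(cm)),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> acc %.2f%%  precision %.3f  recall ",
                     "%.3f  F1 %.3f  kappa %.4f\n"),
              100 * x$acc, x$precision, x$recall, x$f1, x$kappa))
  cm <- x$confusion
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", cm["TP"], cm["FN"],
              cm["FP"], cm["TN"]))
  invisible(x)
}

#' Confusion table with row-normalized percentages
#'
#' @param report an `eval_report`.
#' @param path optional CSV path for export.
#' @return A list with `counts` (2x2, true x predicted, positive class
#'   first) and `percent` (rows normalized to 100).
#' @export
confusion_table <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  cm <- report$confusion
  counts <- matrix(c(cm["TP"], cm["FN"], cm["FP"], cm["TN"]), 2L, 2L,
                   byrow = TRUE,
                   dimnames = list(true = c("infested", "healthy"),
                                   pred = c("infested", "healthy")))
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs == 0, 1, rs)
  if (!is.null(path)) {
    df <- as.data.frame(as.table(counts))
    names(df) <- c("true", "pred", "count")
    df$percent <- as.data.frame(as.table(percent))$Freq
    write.csv(df, path, row.names = FALSE)
  }
  list(counts = counts, percent = percent)
}
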
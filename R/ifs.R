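#' Classifier specifications for LOOCV scoring
#'
#' A classifier spec is a list with a `name`, a `fit(x, y)` function and a
#' `predict(model, x)` function (`x` samples x features). `svm_classifier()`
#' is the pipeline default: C-classification with an RBF kernel, `cost = 1`,
#' `gamma = 1/n_features`, one-vs-one multiclass, and features standardized
#' to zero mean / unit variance using training-fold statistics only (the
#' defaults of [e1071::svm()]). `knn_classifier()` is a deterministic
#' nearest-neighbour alternative used mainly for hand-traceable tests.
#'
#' @param kernel,cost Passed to [e1071::svm()].
#' @param scale Standardize features inside each training fold (default TRUE).
#' @return A classifier spec list.
#' @export
svm_classifier <- function(kernel = "radial", cost = 1, scale = TRUE) {
  list(
    name = sprintf("svm-%s", kernel),
    fit = function(x, y) {
      # constant columns cannot be standardized; e1071 warns and leaves them
      sc <- if (isTRUE(scale)) apply(x, 2, function(col) stats::sd(col) > 0) else FALSE
      e1071::svm(x, y, type = "C-classification", kernel = kernel,
                 cost = cost, scale = sc)
    },
    predict = function(model, x) as.character(predict(model, x))
  )
}

#' @rdname svm_classifier
#' @param k Number of neighbours for `knn_classifier` (default 1).
#' @export
knn_classifier <- function(k = 1) {
  list(
    name = sprintf("%d-nn", k),
    fit = function(x, y) list(x = x, y = y),
    predict = function(model, x)
      as.character(class::knn(model$x, x, model$y, k = k))
  )
}

#' Leave-one-out cross-validation of a classifier on an expression matrix
#'
#' For each sample in turn, trains on all other samples and predicts the
#' held-out one; accuracy is the fraction of correct predictions and the
#' confusion matrix accumulates actual-vs-predicted counts over all folds.
#' Samples are sorted by id before folding so the result is independent of
#' input column order for any deterministic classifier.
#'
#' @param x An [expr_matrix()] already restricted to the feature set under
#'   evaluation; every phase must have at least two samples.
#' @param classifier A classifier spec, see [svm_classifier()].
#' @return List with `accuracy` and `confusion` (rows = actual phases,
#'   columns = predicted, in phase-level order).
#' @export
loocv_evaluate <- function(x, classifier = svm_classifier()) {
  stopifnot(inherits(x, "expr_matrix"))
  y <- x$labels
  if (nlevels(droplevels(y)) < 2) stop("LOOCV needs >= 2 phases")
  ord <- order(sample_ids(x))
  xt <- t(x$values)[ord, , drop = FALSE]
  y <- y[ord]
  n <- length(y)
  pred <- character(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(droplevels(y)))
      stop("training fold lost phase '",
           setdiff(levels(droplevels(y)), levels(ytr)), "'")
    model <- classifier$fit(xt[-i, , drop = FALSE], ytr)
    pred[i] <- classifier$predict(model, xt[i, , drop = FALSE])
  }
  confusion <- table(actual = factor(y, levels = levels(x$labels)),
                     predicted = factor(pred, levels = levels(x$labels)))
  confusion <- unclass(confusion)
  list(accuracy = sum(pred == as.character(y)) / n, confusion = confusion)
}

#' Overall accuracy from a confusion matrix
#'
#' @param confusion Square count matrix, rows = actual, columns = predicted.
#' @return `trace / total`, the fraction of correctly classified samples.
#' @examples
#' cm <- rbind(c(47, 12, 6), c(2, 58, 4), c(1, 3, 33))
#' overall_accuracy(cm)  # 138/166
#' @export
overall_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

#' Pick the optimal signature size from an accuracy curve
#'
#' Formalizes the "small feature set on the accuracy plateau" rule: the
#' smallest evaluated size whose accuracy is within `epsilon` of the best
#' accuracy on the grid.
#'
#' @param points Data frame with columns `n_features` and `accuracy`.
#' @param epsilon Plateau tolerance (default 0.005).
#' @return The selected `n_features`.
#' @examples
#' pts <- data.frame(n_features = c(10, 50, 134, 500),
#'                   accuracy = c(0.80, 0.829, 0.831, 0.832))
#' select_optimal(pts)  # 50
#' @export
select_optimal <- function(points, epsilon = 0.005) {
  stopifnot(nrow(points) > 0, epsilon >= 0)
  ok <- points$accuracy >= max(points$accuracy) - epsilon
  min(points$n_features[ok])
}

#' Incremental feature selection over a feature ranking
#'
#' Builds the nested top-`N` prefixes of the ranking for every `N` on the
#' grid, scores each by classifier LOOCV, and selects the smallest size on
#' the accuracy plateau (see [select_optimal()]).
#'
#' @param ranking A `feature_ranking` from [mcfs_rank()].
#' @param x The [expr_matrix()] the ranking refers to.
#' @param grid_max Largest prefix size to evaluate (default
#'   `min(1000, n ranked features)`).
#' @param step Grid step (default 1, i.e. every size up to `grid_max`).
#' @param grid Explicit increasing vector of sizes; overrides
#'   `grid_max`/`step`.
#' @param classifier Classifier spec (default [svm_classifier()]).
#' @param epsilon Plateau tolerance passed to [select_optimal()].
#' @return An object of class `ifs_curve`: list with `points` (data frame
#'   `n_features`, `accuracy`), `grid`, `selected_n`, `selected_features`
#'   (the top `selected_n` feature ids), `confusion` (LOOCV confusion matrix
#'   at the selected size) and `accuracy` (its overall accuracy).
#' @export
ifs_run <- function(ranking, x, grid_max = NULL, step = 1, grid = NULL,
                    classifier = svm_classifier(), epsilon = 0.005) {
  stopifnot(inherits(x, "expr_matrix"))
  ranked <- ranking$feature_id
  if (is.null(grid)) {
    if (is.null(grid_max)) grid_max <- min(1000L, length(ranked))
    if (grid_max < 1) stop("grid_max must be >= 1")
    grid <- unique(c(seq(1L, grid_max, by = step), grid_max))
  }
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (max(grid) > length(ranked))
    stop("grid exceeds the number of ranked features")
  evals <- lapply(grid, function(n) {
    loocv_evaluate(subset_features(x, ranked[seq_len(n)]), classifier)
  })
  points <- data.frame(n_features = grid,
                       accuracy = vapply(evals, `[[`, numeric(1), "accuracy"))
  selected_n <- select_optimal(points, epsilon)
  sel <- evals[[match(selected_n, grid)]]
  structure(list(points = points, grid = grid, selected_n = selected_n,
                 selected_features = ranked[seq_len(selected_n)],
                 confusion = sel$confusion, accuracy = sel$accuracy),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("ifs_curve: %d grid points, selected %d features (LOOCV accuracy %.3f)\n",
              nrow(x$points), x$selected_n, x$accuracy))
  invisible(x)
}

#' Write incremental-feature-selection outputs as TSV
#'
#' `write_ifs_curve` writes the accuracy curve (`n_features<TAB>accuracy`);
#' `write_signature` writes the selected feature ids, one per line with a
#' `rank` column; `write_confusion` writes the confusion matrix with labeled
#' rows (actual) and columns (predicted).
#'
#' @param curve An `ifs_curve` from [ifs_run()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  pts <- curve$points
  pts$accuracy <- format(pts$accuracy, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curve)
}

#' @rdname write_ifs_curve
#' @export
write_signature <- function(curve, path) {
  df <- data.frame(rank = seq_along(curve$selected_features),
                   feature_id = curve$selected_features)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curve)
}

#' @rdname write_ifs_curve
#' @export
write_confusion <- function(curve, path) {
  cm <- as.data.frame.matrix(curve$confusion)
  cm <- cbind(actual = rownames(curve$confusion), cm)
  utils::write.table(cm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curve)
}
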
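#' Stratified cross-validation of descriptor tables
#'
#' @name crossval
NULL

#' Labelled dataset container
#'
#' @param X numeric `n x p` descriptor matrix (finite entries).
#' @param y class labels (factor or coercible).
#' @param image_ids optional identifiers.
#' @return A `labelled_dataset`.
#' @export
labelled_dataset <- function(X, y, image_ids = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite descriptor entries")
  y <- factor(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (any(table(y) < 2L)) stop("every class needs at least 2 members")
  structure(list(X = X, y = y,
                 image_ids = image_ids %||% seq_len(nrow(X))),
            class = "labelled_dataset")
}

# fold ids 1..k, stratified: per-class proportions within one sample of the
# global proportions. Uses the current RNG state.
stratified_fold_ids <- function(y, k) {
  y <- factor(y)
  out <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold per class so small classes spread evenly
    out[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  out
}

#' Cross-validated accuracy of one classifier
#'
#' Stratified k-fold cross-validation. Feature standardisation (z-score)
#' for NB and SVM is fitted on each training fold only. The summary
#' accuracy is the percentage of correct predictions pooled over folds
#' (equivalently, the fold-size-weighted mean of per-fold accuracies).
#'
#' @param data a [labelled_dataset()].
#' @param classifier_id one of `"NB"`, `"LMT"`, `"RT"`, `"RF"`, `"SVM"`, or
#'   a [make_classifier()] object.
#' @param k number of folds (default 10). If a class has fewer than `k`
#'   members stratification degrades gracefully (that class simply misses
#'   some folds).
#' @param seed integer seed controlling fold assignment and the stochastic
#'   learners.
#' @return A `cv_result` with fields `classifier_id`, `accuracy`
#'   (percentage), `fold_accuracies`, `fold_sizes`, `seed`.
#' @export
crossval_accuracy <- function(data, classifier_id, k = 10L,
                              seed = 20120405L) {
  stopifnot(inherits(data, "labelled_dataset"))
  if (k < 2L) stop("k must be at least 2")
  clf <- if (inherits(classifier_id, "tf_classifier")) classifier_id
         else make_classifier(classifier_id)
  set.seed(seed)
  fold_id <- stratified_fold_ids(data$y, k)
  standardise <- clf$id %in% c("NB", "SVM")
  fold_acc <- numeric(k)
  fold_n <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    if (!any(!tr)) { fold_acc[f] <- NA_real_; next }
    Xtr <- data$X[tr, , drop = FALSE]
    Xte <- data$X[!tr, , drop = FALSE]
    if (standardise) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
    }
    model <- fit_classifier(clf, Xtr, droplevels(data$y[tr]))
    pred <- predict(model, Xte)
    fold_n[f] <- sum(!tr)
    fold_acc[f] <- 100 * mean(as.character(pred) == as.character(data$y[!tr]))
  }
  ok <- !is.na(fold_acc)
  structure(list(classifier_id = clf$id,
                 accuracy = sum(fold_acc[ok] * fold_n[ok]) / sum(fold_n[ok]),
                 fold_accuracies = fold_acc, fold_sizes = fold_n,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: %.2f%% (seed %d)>\n",
              x$classifier_id, x$accuracy, x$seed))
  invisible(x)
}

#' Accuracy table over experimental conditions
#'
#' Evaluates each classifier on each condition's dataset, producing the
#' classifiers x conditions matrix of percentage accuracies plus the
#' per-classifier row mean ("Avg." column).
#'
#' @param datasets named list mapping condition label to
#'   [labelled_dataset()].
#' @param classifiers character vector of classifier ids.
#' @param k folds.
#' @param seed integer seed.
#' @param colour_space annotation string.
#' @return An `accuracy_table`: matrix with an `Avg.` column and attributes
#'   `colour_space`, `seed`.
#' @export
accuracy_table <- function(datasets, classifiers = c("NB", "LMT", "RT", "RF", "SVM"),
                           k = 10L, seed = 20120405L, colour_space = "gray") {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be a named list of conditions")
  vals <- matrix(NA_real_, length(classifiers), length(datasets),
                 dimnames = list(classifiers, names(datasets)))
  for (ci in seq_along(classifiers)) {
    for (di in seq_along(datasets)) {
      vals[ci, di] <- crossval_accuracy(datasets[[di]], classifiers[ci],
                                        k = k, seed = seed)$accuracy
    }
  }
  as_accuracy_table(vals, colour_space = colour_space, seed = seed)
}

#' Construct an accuracy table from a plain matrix
#'
#' @param values classifiers x conditions matrix of percentages.
#' @param colour_space annotation string.
#' @param seed optional seed annotation.
#' @return An `accuracy_table` with the `Avg.` column appended.
#' @export
as_accuracy_table <- function(values, colour_space = "gray", seed = NA) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("accuracy table has missing cells")
  if (any(values < 0 | values > 100)) stop("accuracies must lie in [0, 100]")
  out <- cbind(values, `Avg.` = rowMeans(values))
  structure(out, class = c("accuracy_table", "matrix"),
            colour_space = colour_space, seed = seed)
}

#' Condition values (without the Avg. column) of an accuracy table
#'
#' @param tab an `accuracy_table`.
#' @return Numeric matrix of the per-condition cells.
#' @export
accuracy_values <- function(tab) {
  m <- unclass(tab)
  m[, colnames(m) != "Avg.", drop = FALSE]
}
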
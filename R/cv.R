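# Repeated stratified k-fold cross-validation, confusion-matrix aggregation
# and per-class one-vs-rest metrics.

# evaluate expr with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Build a (stratified) k-fold plan
#'
#' Assigns every sample to one of `k` validation folds.  With
#' `stratified = TRUE` (default) each class is spread as evenly as possible
#' across folds while keeping overall fold sizes within one of each other —
#' for 49 samples and `k = 10` this gives nine folds of 5 and one of 4.
#' Deterministic given `seed`.
#'
#' @param labels Class labels (length S).
#' @param k Number of folds, `2 <= k <= S`.
#' @param seed Integer seed fixing the assignment.
#' @param stratified Spread each class evenly across folds (default `TRUE`).
#' @return Object of class `"fold_plan"`: list with `k`, `seed`,
#'   `stratified` and `assignments` (integer fold index in `1..k` per
#'   sample).
#' @examples
#' plan <- make_folds(rep(c("HC", "LHL", "RHL"), c(20, 15, 14)), 10, seed = 7)
#' sort(tabulate(plan$assignments, 10))  # 4 5 5 5 5 5 5 5 5 5
#' @export
make_folds <- function(labels, k, seed, stratified = TRUE) {
  S <- length(labels)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k != round(k)) {
    stop("'k' must be an integer >= 2")
  }
  k <- as.integer(k)
  if (k > S) stop(sprintf("k = %d exceeds the number of samples S = %d", k, S))
  labels <- as.character(labels)
  assignments <- integer(S)
  .with_seed(seed, {
    if (!stratified) {
      assignments <- sample(rep_len(seq_len(k), S))
    } else {
      totals <- integer(k)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        n_c <- length(idx)
        per_fold <- rep(n_c %/% k, k)
        r <- n_c %% k
        if (r > 0L) {
          # extras go to the currently smallest folds, ties broken at random
          ord <- order(totals, sample.int(k))
          per_fold[ord[seq_len(r)]] <- per_fold[ord[seq_len(r)]] + 1L
        }
        assignments[idx] <- rep.int(seq_len(k), per_fold)
        totals <- totals + per_fold
      }
    }
  })
  structure(list(k = k, seed = seed, stratified = stratified,
                 assignments = assignments),
            class = "fold_plan")
}

#' Confusion matrix of true vs predicted labels
#'
#' @param true,pred Label vectors of equal length.
#' @param classes Class order for rows/columns; defaults to the union of the
#'   observed labels in first-appearance order.
#' @return Object of class `"confusion_matrix"`: an integer C x C matrix,
#'   rows = true class, columns = predicted class.
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_matrix <- function(true, pred, classes = NULL) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (is.null(classes)) classes <- unique(c(as.character(true),
                                            as.character(pred)))
  m <- table(factor(true, levels = classes), factor(pred, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain count matrix to a confusion matrix
#'
#' @param counts Square numeric matrix of non-negative counts, rows = true
#'   class, columns = predicted class, with matching dimnames.
#' @return A `"confusion_matrix"`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion matrix entries must be non-negative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- colnames(counts) %||% paste0("C", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) colnames(counts) <- rownames(counts)
  out <- matrix(as.integer(round(counts)), nrow = nrow(counts),
                dimnames = list(true = rownames(counts),
                                predicted = colnames(counts)))
  structure(out, class = c("confusion_matrix", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  cat(sprintf("overall accuracy: %.2f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' The percentage of correctly classified samples:
#' `100 * trace / total`.
#'
#' @param cm A `"confusion_matrix"` (or square count matrix).
#' @return Accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  cm <- unclass(as_confusion_matrix(cm))
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Per-class one-vs-rest metrics
#'
#' Collapses the multiclass confusion matrix to one class versus the rest:
#' `TP = cm[c, c]`, `FN` = rest of row `c`, `FP` = rest of column `c`,
#' `TN` = remainder; then sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and accuracy `(TP+TN)/total`, all
#' in percent.  A zero denominator yields `NA` (an undefined metric is
#' reported as such, never as 0 or 100).
#'
#' @param cm A `"confusion_matrix"` (or square count matrix).
#' @param class Optional single class name; default all classes.
#' @return Data frame with one row per class and columns `class`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy` (percent,
#'   unrounded; round to 2 decimals for table-style reporting).
#' @examples
#' cm <- as_confusion_matrix(rbind(HC  = c(194, 4, 2),
#'                                 LHL = c(6, 141, 3),
#'                                 RHL = c(4, 5, 131)))
#' round(class_metrics(cm)[, -1], 2)
#' @export
class_metrics <- function(cm, class = NULL) {
  cm <- unclass(as_confusion_matrix(cm))
  classes <- rownames(cm)
  if (!is.null(class)) {
    if (!class %in% classes) stop(sprintf("class '%s' not in matrix", class))
    classes <- class
  }
  tot <- sum(cm)
  rat <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  rows <- lapply(classes, function(cl) {
    TP <- cm[cl, cl]
    FN <- sum(cm[cl, ]) - TP
    FP <- sum(cm[, cl]) - TP
    TN <- tot - TP - FN - FP
    data.frame(class = cl,
               sensitivity = rat(TP, TP + FN),
               specificity = rat(TN, TN + FP),
               precision   = rat(TP, TP + FP),
               accuracy    = rat(TP + TN, tot),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated k-fold cross-validation of the DAG-SVM
#'
#' Runs `runs` independent repetitions of stratified `k`-fold
#' cross-validation: in each repetition a fresh fold plan is drawn (run `r`
#' uses seed `seed + r - 1`), a [dag_svm()] is trained on the training folds
#' (feature standardization uses training-fold statistics only) and the
#' held-out fold is predicted.  Validation confusion counts are accumulated
#' over all folds and runs, so the aggregate confusion-matrix total is
#' `runs * S`.
#'
#' @param features Numeric feature matrix (rows = samples).
#' @param labels Class labels aligned with `features`.
#' @param k Folds per repetition (default 10).
#' @param runs Repetitions (default 10, i.e. a 10 x 10-fold protocol).
#' @param cost Error penalty for every pairwise SVM (default 0.05).
#' @param seed Master seed; per-run fold seeds are derived from it.
#' @param standardize Z-score features per training fold (default `TRUE`).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param class_order Optional fixed class ordering for the DAG.
#' @return Object of class `"dag_svm_cv"`: `fold_correct` and `fold_total`
#'   (`runs x k` matrices), `confusion` (aggregate over all runs),
#'   `per_run_accuracy` (percent), `mean_accuracy` (their average), and the
#'   configuration.
#' @examples
#' set.seed(3)
#' x <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 6), 15))
#' y <- rep(c("A", "B"), each = 15)
#' cv <- cv_dag_svm(x, y, k = 5, runs = 2, cost = 1, seed = 1)
#' cv$mean_accuracy
#' @export
cv_dag_svm <- function(features, labels, k = 10L, runs = 10L, cost = 0.05,
                       seed = 1L, standardize = TRUE, stratified = TRUE,
                       class_order = NULL) {
  features <- as.matrix(features)
  S <- nrow(features)
  if (S != length(labels)) stop("features/labels length mismatch")
  if (!is.numeric(runs) || runs < 1L) stop("'runs' must be >= 1")
  runs <- as.integer(runs)
  labels <- as.character(labels)
  if (is.null(class_order)) class_order <- unique(labels)
  fold_correct <- fold_total <- matrix(0L, runs, k,
    dimnames = list(paste0("run", seq_len(runs)), paste0("F", seq_len(k))))
  agg <- matrix(0L, length(class_order), length(class_order),
                dimnames = list(true = class_order, predicted = class_order))
  for (r in seq_len(runs)) {
    plan <- make_folds(labels, k, seed = seed + r - 1L,
                       stratified = stratified)
    for (fold in seq_len(k)) {
      val <- plan$assignments == fold
      y_tr <- labels[!val]
      missing_cl <- setdiff(class_order, unique(y_tr))
      if (length(missing_cl) > 0L) {
        stop(sprintf("run %d fold %d: training folds lack class %s",
                     r, fold, paste(missing_cl, collapse = ", ")))
      }
      fit <- dag_svm(features[!val, , drop = FALSE], y_tr, cost = cost,
                     standardize = standardize, class_order = class_order)
      pred <- predict(fit, features[val, , drop = FALSE])
      truth <- labels[val]
      fold_correct[r, fold] <- sum(pred == truth)
      fold_total[r, fold] <- length(truth)
      agg <- agg + unclass(confusion_matrix(truth, pred,
                                            classes = class_order))
    }
  }
  per_run <- 100 * rowSums(fold_correct) / rowSums(fold_total)
  structure(list(
    fold_correct = fold_correct, fold_total = fold_total,
    confusion = structure(agg, class = c("confusion_matrix", "matrix")),
    per_run_accuracy = per_run,
    mean_accuracy = mean(per_run),
    config = list(k = k, runs = runs, cost = cost, seed = seed,
                  standardize = standardize, stratified = stratified,
                  class_order = class_order)
  ), class = "dag_svm_cv")
}

#' @export
print.dag_svm_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%d x %d-fold cross-validation of DAG-SVM (cost %g, seed %d)\n",
              cfg$runs, cfg$k, cfg$cost, cfg$seed))
  cat(sprintf("  per-run accuracy (%%): %s\n",
              paste(sprintf("%.2f", x$per_run_accuracy), collapse = " ")))
  cat(sprintf("  mean accuracy: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}

#' @export
summary.dag_svm_cv <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$confusion)
  cat("\nPer-class one-vs-rest metrics (%):\n")
  m <- class_metrics(object$confusion)
  m[, -1] <- round(m[, -1], 2)
  print(m, row.names = FALSE)
  invisible(object)
}

#' Accuracy versus decomposition level
#'
#' Runs the full pipeline — wavelet-entropy extraction at each requested
#' decomposition level followed by repeated k-fold cross-validation of the
#' DAG-SVM — and tabulates the overall accuracy per level, together with the
#' feature count `3n + 1`.
#'
#' @param images List of image matrices.
#' @param labels Class labels aligned with `images`.
#' @param levels Integer vector of decomposition levels (e.g. `1:4`).
#' @param fb A [wavelet_filter_bank()] (default bior5.5).
#' @param ... Passed to [cv_dag_svm()] (`k`, `runs`, `cost`, `seed`, ...).
#' @return Data frame with columns `level`, `n_features`,
#'   `mean_accuracy` (percent).
#' @export
level_sweep <- function(images, labels, levels,
                        fb = wavelet_filter_bank("bior5.5"), ...) {
  stopifnot(length(levels) >= 1L)
  rows <- lapply(levels, function(n) {
    feats <- wavelet_entropy_batch(images, fb, n)
    cv <- cv_dag_svm(feats, labels, ...)
    data.frame(level = as.integer(n), n_features = 3L * as.integer(n) + 1L,
               mean_accuracy = cv$mean_accuracy)
  })
  do.call(rbind, rows)
}
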
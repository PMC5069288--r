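# Decision directed acyclic graph (DDAG) multiclass SVM.
#
# One soft-margin linear SVM per unordered class pair — (C-1)C/2 in total —
# wired as a rooted elimination DAG: each node evaluates one pairwise
# classifier between the first and last class still in play and eliminates
# one of them; after C-1 evaluations a single class remains.
#
# For the pair (i, j), i before j in the class order, class i is the SVM's
# positive class, so a score L_ij(x) >= 0 (o_ij = sgn(L_ij) = +1) asserts
# "x is not in class j" and eliminates j; a negative score eliminates i.

#' Fit a DAG-SVM multiclass classifier
#'
#' Trains one [linear_svm()] on every unordered pair of classes (each model
#' sees only the samples of its two classes) and composes them as a decision
#' DAG.  For `C = 3` hearing-loss classes in the order HC, LHL, RHL this is
#' the three-classifier graph HC-v-RHL at the root, then HC-v-LHL and
#' LHL-v-RHL.
#'
#' Features are z-scored with statistics computed from `x` (the training
#' data) by default, because wavelet entropies live on different scales
#' across subbands; the same statistics are re-applied at prediction time.
#' Set `standardize = FALSE` to train on raw features.
#'
#' @param x Numeric feature matrix (rows = samples, e.g. a
#'   [wavelet_entropy_batch()] table).
#' @param y Class labels, at least two distinct values; each class needs at
#'   least one sample (two or more recommended).
#' @param cost Error penalty passed to every pairwise SVM (default 0.05).
#' @param standardize Z-score features with training statistics
#'   (default `TRUE`).  Constant features get unit scale.
#' @param class_order Optional character vector fixing the class ordering
#'   (and hence the DAG node layout).  Defaults to factor level order, or
#'   first appearance order for non-factor labels.
#' @return An object of class `"dag_svm"`: `class_names`, `models` (named
#'   `"i vs j"`), `cost`, `center`/`scale` (or `NULL`), and any feature
#'   metadata (`wavelet`, `level`) carried by `x`.
#' @seealso [predict.dag_svm()], [cv_dag_svm()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10),
#'            matrix(rnorm(20, 8), 10))
#' y <- rep(c("HC", "LHL", "RHL"), each = 10)
#' fit <- dag_svm(x, y, cost = 1)
#' table(predict(fit, x), y)
#' @export
dag_svm <- function(x, y, cost = 0.05, standardize = TRUE,
                    class_order = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(class_order)) {
    class_order <- if (is.factor(y)) levels(droplevels(y)) else
      as.character(unique(y))
  }
  y <- as.character(y)
  if (!all(y %in% class_order)) {
    stop("labels outside 'class_order': ",
         paste(setdiff(y, class_order), collapse = ", "))
  }
  C <- length(class_order)
  if (C < 2L) stop("need at least 2 classes")
  counts <- table(factor(y, levels = class_order))
  if (any(counts == 0L)) {
    stop("class with zero samples: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  }
  center <- scale_ <- NULL
  xs <- x
  if (isTRUE(standardize)) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, stats::sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  }
  models <- list()
  for (i in seq_len(C - 1L)) {
    for (j in seq.int(i + 1L, C)) {
      ci <- class_order[i]; cj <- class_order[j]
      sel <- y %in% c(ci, cj)
      models[[paste(ci, "vs", cj)]] <-
        linear_svm(xs[sel, , drop = FALSE],
                   factor(y[sel], levels = c(ci, cj)), cost = cost)
    }
  }
  structure(list(class_names = class_order, models = models, cost = cost,
                 center = center, scale = scale_,
                 standardize = isTRUE(standardize),
                 wavelet = attr(x, "wavelet"), level = attr(x, "level")),
            class = "dag_svm")
}

# one DDAG descent; returns final class plus the node-by-node trace
.dag_descend <- function(object, xrow) {
  cls <- object$class_names
  remaining <- seq_along(cls)
  trace <- data.frame(node = character(0), score = numeric(0),
                      eliminated = character(0), stringsAsFactors = FALSE)
  while (length(remaining) > 1L) {
    i <- remaining[1L]; j <- remaining[length(remaining)]
    m <- object$models[[paste(cls[i], "vs", cls[j])]]
    s <- decision_score(m, xrow)
    if (s >= 0) {          # sgn(0) = +1: x is not in class j
      out <- j; remaining <- remaining[-length(remaining)]
    } else {
      out <- i; remaining <- remaining[-1L]
    }
    trace <- rbind(trace, data.frame(node = paste(cls[i], "vs", cls[j]),
                                     score = s, eliminated = cls[out],
                                     stringsAsFactors = FALSE))
  }
  list(class = cls[remaining], trace = trace)
}

#' Predict from a DAG-SVM
#'
#' Descends the elimination DAG: exactly `C - 1` pairwise decision scores
#' are evaluated per sample, each eliminating one class.
#'
#' @param object A [dag_svm()] fit.
#' @param newdata Feature vector or matrix (columns must match training).
#' @param type `"class"` (default) for the predicted labels, `"trace"` for a
#'   list of per-sample elimination traces (node, score, eliminated class).
#' @param ... Unused.
#' @return Character vector of class names, or a list of trace data frames.
#' @export
predict.dag_svm <- function(object, newdata, type = c("class", "trace"), ...) {
  type <- match.arg(type)
  A <- length(object$models[[1L]]$w)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != A) {
    stop(sprintf("expected %d features, got %d", A, ncol(newdata)))
  }
  if (object$standardize) {
    newdata <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  }
  res <- lapply(seq_len(nrow(newdata)), function(r) {
    .dag_descend(object, newdata[r, ])
  })
  if (type == "trace") return(lapply(res, `[[`, "trace"))
  vapply(res, `[[`, character(1), "class")
}

#' @export
print.dag_svm <- function(x, ...) {
  C <- length(x$class_names)
  cat(sprintf("DAG-SVM: %d classes (%s), %d pairwise linear SVMs, cost = %g\n",
              C, paste(x$class_names, collapse = ", "),
              length(x$models), x$cost))
  if (!is.null(x$wavelet)) {
    cat(sprintf("  features: %d wavelet entropies (%s, level %d)\n",
                length(x$models[[1L]]$w), x$wavelet, x$level))
  }
  if (x$standardize) cat("  features z-scored with training statistics\n")
  invisible(x)
}

#' @export
summary.dag_svm <- function(object, ...) {
  print(object)
  for (nm in names(object$models)) {
    m <- object$models[[nm]]
    cat(sprintf("  %-18s objective %.5g, support vectors %d\n",
                nm, m$objective, sum(m$alpha > 1e-8)))
  }
  invisible(object)
}

#' @export
coef.dag_svm <- function(object, ...) {
  do.call(rbind, lapply(object$models, coef))
}
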
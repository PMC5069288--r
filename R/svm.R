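# Soft-margin binary linear SVM.
#
# Primal problem:  min_{w,b,xi}  1/2 ||w||^2 + cost * sum_n xi_n
#                  s.t.  y_n (w . x_n - b) >= 1 - xi_n,  xi_n >= 0.
# Solved via its dual by sequential minimal optimization (SMO) with
# maximal-violating-pair working-set selection; the decision score is
# L(x) = w . x - b, with L > 0 voting for the positive class and ties
# (L == 0) broken toward the positive class.

# SMO on the dual: max sum(a) - 1/2 a' Q a, 0 <= a <= C, y'a = 0,
# Q = (y y') * (X X').  Deterministic: a starts at 0, first-index tie-breaks.
.smo <- function(K, y, C, tol = 1e-10, max_iter = 200000L) {
  S <- length(y)
  Q <- (y %o% y) * K
  a <- numeric(S)
  G <- rep(-1, S)               # G = Q a - 1
  eps <- 1e-12
  it <- 0L
  repeat {
    it <- it + 1L
    v <- -y * G
    up  <- (y > 0 & a < C - eps) | (y < 0 & a > eps)
    low <- (y < 0 & a < C - eps) | (y > 0 & a > eps)
    m  <- max(v[up])
    Mv <- min(v[low])
    if (m - Mv < tol || it > max_iter) break
    i <- which(up)[which.max(v[up])]
    j <- which(low)[which.min(v[low])]
    eta <- max(K[i, i] + K[j, j] - 2 * K[i, j], 1e-12)
    # E_i - E_j with the bias cancelling
    dE <- y[i] * G[i] - y[j] * G[j]
    aj_old <- a[j]; ai_old <- a[i]
    aj <- aj_old + y[j] * dE / eta
    if (y[i] != y[j]) {
      Lo <- max(0, aj_old - ai_old); Hi <- min(C, C + aj_old - ai_old)
    } else {
      Lo <- max(0, ai_old + aj_old - C); Hi <- min(C, ai_old + aj_old)
    }
    aj <- min(max(aj, Lo), Hi)
    ai <- ai_old + y[i] * y[j] * (aj_old - aj)
    a[i] <- ai; a[j] <- aj
    G <- G + Q[, i] * (ai - ai_old) + Q[, j] * (aj - aj_old)
  }
  if (it > max_iter) {
    warning("SMO did not reach the requested tolerance within max_iter")
  }
  free <- a > eps & a < C - eps
  b <- if (any(free)) -mean(v[free]) else -(m + Mv) / 2
  list(alpha = a, b = b, iterations = it)
}

#' Train a soft-margin binary linear SVM
#'
#' Fits the linear soft-margin SVM by solving its dual with a deterministic
#' SMO solver.  The first class level is mapped to +1 (the positive class),
#' the second to -1.  Features are used as given; standardization, when
#' wanted, is applied by the caller (see [dag_svm()], where it is the
#' default).
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels with exactly two distinct values (factor, character or
#'   numeric); both must be present.
#' @param cost Error penalty (the `C`-type penalty weighting the slack sum),
#'   `> 0`.  Default 0.05, the pipeline's working value.
#' @param tol SMO duality-gap stopping tolerance.
#' @param max_iter Iteration cap for the SMO loop.
#' @return An object of class `"linear_svm"`: weights `w`, bias `b`
#'   (decision score `w . x - b`), `cost`, per-sample slack `xi`, the primal
#'   `objective`, dual coefficients `alpha`, and `pos_class`/`neg_class`.
#' @examples
#' # two 1-D points at -1 and +1: hard-margin solution is w = 1, b = 0
#' fit <- linear_svm(matrix(c(1, -1), ncol = 1), c("pos", "neg"), cost = 100)
#' c(fit$w, fit$b)
#' @export
linear_svm <- function(x, y, cost = 0.05, tol = 1e-10, max_iter = 200000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("features contain non-finite values")
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost <= 0) {
    stop("'cost' (error penalty) must be a positive scalar")
  }
  f <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(y))
  if (nlevels(f) != 2L) {
    stop(sprintf("binary SVM needs exactly 2 classes, got %d (%s)",
                 nlevels(f), paste(levels(f), collapse = ", ")))
  }
  if (nrow(x) != length(f)) stop("nrow(x) must match length(y)")
  ysign <- ifelse(as.integer(f) == 1L, 1, -1)
  K <- tcrossprod(x)
  sol <- .smo(K, ysign, cost, tol = tol, max_iter = max_iter)
  w <- drop(crossprod(x, sol$alpha * ysign))
  b <- sol$b
  score <- drop(x %*% w) - b
  xi <- pmax(0, 1 - ysign * score)
  structure(list(
    w = w, b = b, cost = cost,
    xi = xi, alpha = sol$alpha,
    objective = 0.5 * sum(w^2) + cost * sum(xi),
    iterations = sol$iterations,
    pos_class = levels(f)[1L], neg_class = levels(f)[2L]
  ), class = "linear_svm")
}

#' Decision score of a binary SVM
#'
#' Returns `L(x) = w . x - b`.  `L > 0` votes for the positive class,
#' `L < 0` for the negative class; `L == 0` is resolved toward the positive
#' class by [predict.linear_svm()].
#'
#' @param model A `"linear_svm"` fit.
#' @param x Numeric vector of length `length(model$w)`, or a matrix with
#'   that many columns.
#' @return Numeric score(s).
#' @export
decision_score <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  A <- length(model$w)
  if (is.matrix(x)) {
    if (ncol(x) != A) stop(sprintf("expected %d features, got %d", A, ncol(x)))
    drop(x %*% model$w) - model$b
  } else {
    if (length(x) != A) {
      stop(sprintf("expected %d features, got %d", A, length(x)))
    }
    sum(x * model$w) - model$b
  }
}

#' @rdname linear_svm
#' @param object,newdata,... Fit, new feature matrix/vector, unused.
#' @param type `"class"` for labels, `"score"` for raw decision values.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- decision_score(object, newdata)
  if (type == "score") return(s)
  ifelse(s >= 0, object$pos_class, object$neg_class)
}

#' @export
coef.linear_svm <- function(object, ...) {
  w <- object$w
  names(w) <- if (is.null(names(w))) paste0("x", seq_along(w)) else names(w)
  c("(bias)" = object$b, w)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("Soft-margin linear SVM: %s (+1) vs %s (-1), cost = %g\n",
              x$pos_class, x$neg_class, x$cost))
  cat(sprintf("  %d features, objective %.6g, sum slack %.4g\n",
              length(x$w), x$objective, sum(x$xi)))
  invisible(x)
}
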
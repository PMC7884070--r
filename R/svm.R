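#' Linear support vector machine (C-classification)
#'
#' Binary max-margin classifier with a linear kernel and fixed
#' regularization `cost` (C = 1 throughout the pipeline unless overridden).
#' The dual problem is solved by a compact SMO solver (compiled code) sized
#' for the small trial counts of leave-one-run-out decoding; this keeps the
#' ~10^4-iteration group permutation tests tractable. The decision rule is
#' `sign(w'x + b)`, with an exact tie (decision value 0) assigned to the
#' first class level — a documented, measure-zero tie-break with continuous
#' features.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param y factor with exactly two levels (first level = positive class),
#'   or a vector coercible to one.
#' @param cost regularization parameter C (default 1).
#' @param eps SMO stopping tolerance on the KKT violation (default 1e-3).
#' @param max_iter iteration cap.
#' @return object of class `linear_svm`: `w`, `b`, `levels`, `alpha`,
#'   `iterations`.
#' @export
svm_train <- function(x, y, cost = 1, eps = 1e-3, max_iter = 100000L) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  lev <- levels(y)
  if (length(lev) != 2 || any(is.na(y))) {
    stop("y must be a two-level factor without NAs")
  }
  if (length(unique(y)) < 2) stop("training data contain only one class")
  yi <- ifelse(y == lev[1], 1L, -1L)
  fit <- svm_linear_fit(x, yi, cost, eps, as.integer(max_iter))
  if (!fit$converged) {
    warning("SVM solver hit the iteration cap (", max_iter, ")")
  }
  structure(list(w = as.numeric(fit$w), b = fit$b, levels = lev,
                 alpha = fit$alpha, iterations = fit$iterations),
            class = "linear_svm")
}

#' Decision values of a linear SVM
#'
#' @param object a `linear_svm`.
#' @param newx matrix of samples.
#' @return numeric vector `w'x + b`; positive values favor the first level.
#' @export
svm_decision <- function(object, newx) {
  as.numeric(as.matrix(newx) %*% object$w + object$b)
}

#' @param ... unused.
#' @rdname svm_train
#' @export
predict.linear_svm <- function(object, newx, ...) {
  d <- svm_decision(object, newx)
  factor(ifelse(d >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}
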
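# Linear soft-margin SVM (hinge loss), solved by SMO on the dual.

#' Train a linear soft-margin SVM
#'
#' Solves min_w,b 0.5 |w|^2 + C * sum_i max(0, 1 - y_i (<w, x_i> + b)) via
#' sequential minimal optimization of the dual with maximal-violating-pair
#' working-set selection. The returned decision function is
#' `<w, x> + b`; class +1 is predicted for non-negative decision values.
#'
#' @param X numeric matrix of training rows.
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param C soft-margin cost, > 0.
#' @param tol KKT violation tolerance of the solver.
#' @return object of class `linear_svm`: `w`, `b`, `alpha`, `C`,
#'   `obj_primal`, `obj_dual`, `iterations`.
#' @export
train_linear_svm <- function(X, y, C = 1, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_arg("labels must be coded -1 / +1")
  if (length(unique(y)) < 2L) stop_arg("both classes must be present")
  if (length(y) != nrow(X)) stop_arg("length(y) must equal nrow(X)")
  C <- check_number(C, "C", lower = 0, strict_lower = TRUE)
  fit <- .svm_smo_cpp(X, y, C, tol)
  structure(c(fit, list(C = C)), class = "linear_svm")
}

#' Predict from a linear SVM
#'
#' @param object a `linear_svm`.
#' @param newdata numeric matrix of rows to score.
#' @param type `"class"` for labels in \{-1, +1\} (decision >= 0 maps to +1)
#'   or `"decision"` for raw decision values.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w))
    stop_arg("newdata has ", ncol(newdata), " columns; model expects ",
             length(object$w))
  dec <- drop(newdata %*% object$w) + object$b
  if (type == "decision") dec else ifelse(dec >= 0, 1, -1)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear soft-margin SVM: ", length(x$w), " features, C = ", x$C,
      ", primal objective ", format(x$obj_primal, digits = 6), "\n", sep = "")
  invisible(x)
}
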
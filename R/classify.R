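# Leave-one-out cross-validation, confusion metrics, ROC/AUC, and the
# permutation significance test for the pre/post classifier.

#' Confusion-matrix metrics
#'
#' accuracy = (TP+TN)/(TP+FN+TN+FP), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), with post-training scans coded positive.
#'
#' @param TP,FN,TN,FP non-negative counts; each class must be non-empty.
#' @return list with the four counts and the three proportions.
#' @export
compute_metrics <- function(TP, FN, TN, FP) {
  for (v in c(TP, FN, TN, FP))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop_arg("counts must be single non-negative integers")
  if (TP + FN == 0) stop_arg("no positive samples: sensitivity undefined")
  if (TN + FP == 0) stop_arg("no negative samples: specificity undefined")
  list(TP = TP, FN = FN, TN = TN, FP = FP,
       accuracy = (TP + TN) / (TP + FN + TN + FP),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP))
}

#' ROC curve and AUC from decision values
#'
#' AUC in the Mann-Whitney form: the probability that a random positive
#' scores above a random negative, counting ties as 1/2 -- identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param decision_values numeric scores (larger = more positive).
#' @param y labels in \{-1, +1\}; both classes required.
#' @return list with `auc` and `roc_points` (data.frame of FPR/TPR, from
#'   (0,0) to (1,1)).
#' @export
roc_auc <- function(decision_values, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L)
    stop_arg("labels must contain both +1 and -1")
  if (length(decision_values) != length(y))
    stop_arg("scores and labels differ in length")
  npos <- sum(y == 1)
  nneg <- sum(y == -1)
  if (stats::sd(decision_values) == 0) {
    warning("constant decision values; AUC = 0.5", call. = FALSE)
    auc <- 0.5
  } else {
    r <- rank(decision_values)  # midranks handle ties
    auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  ord <- order(decision_values, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1)
  fp <- cumsum(y[ord] == -1)
  keep <- c(diff(decision_values[ord]) != 0, TRUE)  # one point per threshold
  roc <- data.frame(fpr = c(0, fp[keep] / nneg), tpr = c(0, tp[keep] / npos))
  list(auc = auc, roc_points = roc)
}

.make_folds <- function(n, subject_ids, scheme) {
  if (scheme == "scan") return(seq_len(n))
  if (is.null(subject_ids))
    stop_arg("subject-level cross-validation needs subject_ids")
  if (length(subject_ids) != n)
    stop_arg("subject_ids must have one entry per row")
  as.integer(factor(subject_ids))
}

#' Leave-one-out cross-validated evaluation of the linear SVM
#'
#' Each cross-validation unit (a subject's two scans by default, or a single
#' scan) is held out in turn; a model trained on the remainder predicts it.
#' Predictions are aggregated into a confusion matrix, Eq-style metrics, and
#' a pooled-decision-value ROC/AUC.
#'
#' @param X feature matrix (scans x features).
#' @param y labels in \{-1, +1\}.
#' @param subject_ids pairing ids, required for `scheme = "subject"`.
#' @param scheme `"subject"` (default) or `"scan"`.
#' @param C soft-margin cost.
#' @param scale_in_fold learn min-max scaling on training rows per fold.
#' @return object of class `classification_metrics`: the counts and
#'   proportions of [compute_metrics()], `auc`, `roc_points`, and the
#'   per-scan `decision`, `prediction`, `fold` vectors.
#' @export
loocv_evaluate <- function(X, y, subject_ids = NULL,
                           scheme = c("subject", "scan"), C = 1,
                           scale_in_fold = FALSE) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_arg("labels must be coded -1 / +1")
  fold <- .make_folds(nrow(X), subject_ids, scheme)
  if (length(unique(fold)) < 2L) stop_arg("need at least 2 CV units")
  fit <- .svm_loocv_cpp(X, y, fold, C, scale_in_fold)
  pred <- fit$prediction
  m <- compute_metrics(TP = sum(pred == 1 & y == 1),
                       FN = sum(pred == -1 & y == 1),
                       TN = sum(pred == -1 & y == -1),
                       FP = sum(pred == 1 & y == -1))
  roc <- roc_auc(fit$decision, y)
  structure(c(m, list(auc = roc$auc, roc_points = roc$roc_points,
                      decision = fit$decision, prediction = pred,
                      fold = fold, scheme = scheme, C = C)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "LOOCV (%s-level): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.4f\n",
    x$scheme, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    x$auc))
  cat(sprintf("confusion: TP %d  FN %d  TN %d  FP %d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Permutation test of the cross-validated accuracy
#'
#' For each of B iterations the training labels are randomly reassigned and
#' the LOOCV accuracy recomputed on the supplied (already selected) feature
#' set; held-out scans are always scored against their true labels. With
#' `pairing = "subject"` (default) each subject's two scans swap labels
#' coherently, preserving the paired design; `pairing = "scan"` assigns
#' every scan an independent random label.
#'
#' Both the plug-in p value `p_raw = #\{null >= observed\}/B` (which can be
#' 0, conventionally reported as "< 1/B") and the add-one corrected
#' `p_add_one = (#\{null >= observed\} + 1)/(B + 1)` are returned.
#'
#' @param X selected feature matrix (scans x features).
#' @param y true labels in \{-1, +1\}.
#' @param subject_ids pairing ids.
#' @param B number of permutations, >= 1.
#' @param seed optional integer seed for the permutation stream.
#' @param scheme cross-validation unit, as in [loocv_evaluate()].
#' @param pairing `"subject"` (coherent within-pair flips) or `"scan"`.
#' @param C soft-margin cost.
#' @param observed observed LOOCV accuracy; computed if missing.
#' @param scale_in_fold learn min-max scaling per fold.
#' @return object of class `permutation_result`: `observed_accuracy`,
#'   `null_accuracies` (length B), `p_raw`, `p_add_one`, `B`, `seed`.
#' @export
permutation_test <- function(X, y, subject_ids = NULL, B = 1000,
                             seed = NULL, scheme = c("subject", "scan"),
                             pairing = c("subject", "scan"), C = 1,
                             observed = NULL, scale_in_fold = FALSE) {
  scheme <- match.arg(scheme)
  pairing <- match.arg(pairing)
  B <- check_count(B, "B")
  X <- as.matrix(X)
  y <- as.numeric(y)
  fold <- .make_folds(nrow(X), subject_ids, scheme)
  if (is.null(observed))
    observed <- loocv_evaluate(X, y, subject_ids, scheme, C,
                               scale_in_fold)$accuracy
  # the feature set is fixed, so one kernel serves every permutation
  # (fold-wise rescaling depends on the fold split only, not the labels,
  # so it keeps the row-based path)
  K <- if (!scale_in_fold) tcrossprod(X)
  one <- function(yb) {
    fit <- if (is.null(K)) .svm_loocv_cpp(X, yb, fold, C, scale_in_fold)
           else .svm_loocv_kernel_cpp(K, yb, fold, C)
    mean(fit$prediction == y)
  }
  run <- function() {
    null_acc <- numeric(B)
    if (pairing == "subject") {
      subj <- as.integer(factor(subject_ids))
      ns <- max(subj)
      for (b in seq_len(B))
        null_acc[b] <- one(y * sample(c(-1, 1), ns, replace = TRUE)[subj])
    } else {
      for (b in seq_len(B))
        null_acc[b] <- one(sample(c(-1, 1), length(y), replace = TRUE))
    }
    null_acc
  }
  null_acc <- if (is.null(seed)) run() else .with_seed(seed, run())
  ge <- sum(null_acc >= observed - 1e-12)
  structure(list(observed_accuracy = observed, null_accuracies = null_acc,
                 p_raw = ge / B, p_add_one = (ge + 1) / (B + 1),
                 B = B, seed = seed, pairing = pairing),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  p_lab <- if (x$p_raw == 0) sprintf("< %.4g", 1 / x$B)
           else sprintf("= %.4g", x$p_raw)
  cat(sprintf(
    "Permutation test (B = %d, %s pairing): observed accuracy %.1f%%, p %s (add-one p = %.4g)\n",
    x$B, x$pairing, 100 * x$observed_accuracy, p_lab, x$p_add_one))
  invisible(x)
}
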
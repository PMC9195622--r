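# Two-stage feature selection: leave-one-out paired t-test screening, then
# accuracy-driven recursive feature elimination around the linear SVM.

#' Paired-sample t test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the differences d = post - pre, with a
#' two-sided p value on n - 1 degrees of freedom.
#'
#' If the differences have zero variance the statistic is undefined: when all
#' differences are exactly zero this returns t = 0, p = 1 (no evidence either
#' way); otherwise t and p are NaN with a warning.
#'
#' @param pre,post equal-length numeric vectors paired by subject, n >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post)) stop_arg("pre and post lengths differ")
  n <- length(pre)
  if (n < 2L) stop_arg("need at least 2 pairs")
  d <- post - pre
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0, n = n))
    warning("zero variance of paired differences; t undefined", call. = FALSE)
    return(list(t = NaN, p = NaN, df = n - 1L, mean_diff = m, n = n))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1L,
       mean_diff = m, n = n)
}

# vectorized paired t over the columns of a difference matrix (subjects x R)
.paired_t_cols <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  t <- ifelse(s == 0, ifelse(m == 0, 0, NaN), m / (s / sqrt(n)))
  p <- ifelse(is.nan(t), NaN,
              ifelse(s == 0, 1, 2 * stats::pt(-abs(t), df = n - 1)))
  list(t = t, p = p)
}

#' Stage-1 screening: leave-one-out paired t tests
#'
#' For each leave-one-out iteration (default unit: subject), a paired t test
#' is run per region on the training subjects' post-minus-pre differences;
#' the returned set is the union over iterations of regions with p < alpha.
#' Under `scheme = "scan"` single scans are held out and only the training
#' set's complete pairs enter the test.
#'
#' @param fm an `alff_features` object.
#' @param alpha screening threshold in (0, 1].
#' @param scheme leave-out unit: `"subject"` (default) or `"scan"`.
#' @return list of class `stage1_result`: `regions` (sorted union),
#'   `per_iteration` (list of per-fold surviving labels), `alpha`, `scheme`.
#' @export
stage1_select <- function(fm, alpha = 0.05, scheme = c("subject", "scan")) {
  stopifnot(inherits(fm, "alff_features"))
  scheme <- match.arg(scheme)
  alpha <- check_number(alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE)
  d_all <- paired_differences(fm)
  subj <- rownames(d_all)
  units <- if (scheme == "subject") subj else seq_len(nrow(fm$values))
  per_iter <- vector("list", length(units))
  for (i in seq_along(units)) {
    if (scheme == "subject") {
      d <- d_all[subj != units[i], , drop = FALSE]
    } else {
      drop_subj <- as.character(fm$subject_ids[as.integer(units[i])])
      d <- d_all[subj != drop_subj, , drop = FALSE]
    }
    if (nrow(d) < 3L) stop_arg("fewer than 3 training pairs in iteration ", i)
    p <- .paired_t_cols(d)$p
    per_iter[[i]] <- fm$region_labels[which(p < alpha)]
  }
  structure(list(regions = sort(unique(unlist(per_iter))),
                 per_iteration = per_iter, alpha = alpha, scheme = scheme),
            class = "stage1_result")
}

# LOOCV accuracy of the linear SVM for a given feature subset
.loocv_accuracy <- function(x, y, fold, C, scale_in_fold = FALSE) {
  fit <- .svm_loocv_cpp(as.matrix(x), as.numeric(y), as.integer(fold),
                        C, scale_in_fold)
  mean(fit$prediction == y)
}

# kernel-driven variant: K is the Gram matrix of the current feature set,
# which feature elimination can downdate by rank-1 terms instead of
# recomputing dot products
.loocv_accuracy_K <- function(K, y, fold, C) {
  fit <- .svm_loocv_kernel_cpp(K, as.numeric(y), as.integer(fold), C)
  mean(fit$prediction == y)
}

#' Accuracy-driven recursive feature elimination (RFE-SVM)
#'
#' Implements the accuracy-driven elimination loop: (a) compute the LOOCV
#' accuracy of the current feature set (`accuracy_0`); (b) for each feature
#' i, the LOOCV accuracy without it (`accuracy_i`); (c) remove the features
#' with `accuracy_i >= accuracy_0`; (d) repeat until no single elimination
#' keeps the accuracy, or one feature remains.
#'
#' With `batch = TRUE` (default) the removable features are deleted
#' simultaneously per round, with two guards that keep the accuracy trace
#' non-decreasing: a batch that would empty the set retains the single
#' feature whose removal-accuracy is highest (ties: lowest region label
#' retained), and a batch whose joint removal would reduce the LOOCV accuracy
#' below `accuracy_0` falls back to removing only the single feature with
#' the highest removal-accuracy (ties: highest label removed). With
#' `batch = FALSE` one feature is removed per round.
#'
#' @param fm an `alff_features` object (>= 2 features).
#' @param scheme cross-validation unit: `"subject"` (both scans of the
#'   held-out subject leave the training set) or `"scan"`.
#' @param svm_cost soft-margin cost C of the linear SVM.
#' @param batch remove per-round batches (default) or one at a time.
#' @param scale_in_fold learn min-max scaling on training rows within each
#'   fold instead of using the globally rescaled features.
#' @return object of class `selection_result`: `stage1_regions` (the input
#'   region set), `stage2_regions` (surviving labels, in column order),
#'   `accuracy_trace` (accuracy_0 per completed round), `removed_per_round`,
#'   `final_accuracy`, `svm_cost`, `scheme`.
#' @export
rfe_select <- function(fm, scheme = c("subject", "scan"), svm_cost = 1,
                       batch = TRUE, scale_in_fold = FALSE) {
  stopifnot(inherits(fm, "alff_features"))
  scheme <- match.arg(scheme)
  svm_cost <- check_number(svm_cost, "svm_cost", lower = 0,
                           strict_lower = TRUE)
  y <- fm$labels
  if (!all(y %in% c(-1, 1)) || length(unique(y)) != 2L)
    stop_arg("labels must contain both +1 and -1")
  if (nrow(fm$values) < 4L) stop_arg("need at least 4 samples")
  fold <- if (scheme == "subject") as.integer(factor(fm$subject_ids))
          else seq_along(y)
  current <- seq_len(ncol(fm$values))
  if (length(current) < 1L) stop_arg("no features to select from")
  trace <- numeric(0)
  removed <- list()
  x <- fm$values
  tol <- 1e-12
  use_kernel <- !scale_in_fold
  repeat {
    if (use_kernel) Kcur <- tcrossprod(x[, current, drop = FALSE])
    acc0 <- if (use_kernel) .loocv_accuracy_K(Kcur, y, fold, svm_cost)
            else .loocv_accuracy(x[, current, drop = FALSE], y, fold,
                                 svm_cost, scale_in_fold)
    trace <- c(trace, acc0)
    if (length(current) == 1L) break
    acc_i <- vapply(seq_along(current), function(j) {
      if (use_kernel)
        .loocv_accuracy_K(Kcur - tcrossprod(x[, current[j]]), y, fold,
                          svm_cost)
      else
        .loocv_accuracy(x[, current[-j], drop = FALSE], y, fold, svm_cost,
                        scale_in_fold)
    }, numeric(1))
    removable <- which(acc_i >= acc0 - tol)
    if (!length(removable)) break
    committed <- FALSE
    if (batch && length(removable) > 1L) {
      if (length(removable) == length(current)) {
        # batch would empty the set: retain the single feature with the
        # highest removal-accuracy (ties: lowest region label retained)
        best <- max(acc_i)
        keep <- which(acc_i >= best - tol)
        after <- current[keep[which.min(fm$region_labels[current[keep]])]]
      } else {
        after <- current[-removable]
      }
      acc_after <- .loocv_accuracy(x[, after, drop = FALSE], y, fold,
                                   svm_cost, scale_in_fold)
      if (acc_after >= acc0 - tol) {
        removed <- c(removed, list(fm$region_labels[setdiff(current, after)]))
        current <- after
        committed <- TRUE
      }
    }
    if (!committed) {
      # single removal: highest removal-accuracy, ties -> highest label out;
      # acc_i >= acc0 guarantees the trace cannot decrease
      best <- max(acc_i[removable])
      cand <- removable[acc_i[removable] >= best - tol]
      drop_j <- cand[which.max(fm$region_labels[current[cand]])]
      removed <- c(removed, list(fm$region_labels[current[drop_j]]))
      current <- current[-drop_j]
    }
  }
  structure(list(stage1_regions = fm$region_labels,
                 stage2_regions = fm$region_labels[current],
                 accuracy_trace = trace,
                 removed_per_round = removed,
                 final_accuracy = trace[length(trace)],
                 svm_cost = svm_cost, scheme = scheme),
            class = "selection_result")
}
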
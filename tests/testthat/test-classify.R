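# Confusion metrics, ROC/AUC, LOOCV evaluation, permutation test.

test_that("confusion metrics reproduce the defining ratios", {
  m <- compute_metrics(TP = 25, FN = 5, TN = 24, FP = 6)
  expect_equal(m$accuracy, 49 / 60, tolerance = 1e-12)
  expect_equal(m$sensitivity, 25 / 30, tolerance = 1e-12)
  expect_equal(m$specificity, 24 / 30, tolerance = 1e-12)
  eq <- compute_metrics(7, 7, 7, 7)
  expect_equal(eq$accuracy, 0.5)
  perfect <- compute_metrics(10, 0, 12, 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  expect_error(compute_metrics(0, 0, 5, 5), "sensitivity undefined")
  expect_error(compute_metrics(5, 5, 0, 0), "specificity undefined")
  expect_error(compute_metrics(-1, 0, 1, 1), "non-negative")
})

test_that("AUC equals the pairwise-comparison oracle", {
  # hand example: 3 of 4 pairs correctly ordered
  r <- roc_auc(c(3, 1, 2, 0), c(1, 1, -1, -1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, -1, -1))$auc, 1)
  # label flip maps AUC to 1 - AUC
  expect_equal(roc_auc(c(3, 1, 2, 0), c(-1, -1, 1, 1))$auc, 0.25)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    y <- c(-1, 1, sign(rnorm(n - 2))); y[y == 0] <- 1
    scores <- if (i %% 3 == 0) sample(1:4, n, TRUE) else rnorm(n)  # ties
    r <- roc_auc(scores, y)
    expect_equal(r$auc, oracle_auc(scores, y), tolerance = 1e-12)
    # ROC endpoints and trapezoid area agree with the rank AUC
    expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0),
                 ignore_attr = TRUE)
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]), c(fpr = 1, tpr = 1))
    pts <- r$roc_points
    area <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(area, r$auc, tolerance = 1e-12)
  }
  expect_warning(rc <- roc_auc(rep(1, 4), c(1, 1, -1, -1)), "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("LOOCV separates the separable and stays at chance on noise", {
  set.seed(12)
  ids <- rep(sprintf("s%02d", 1:10), each = 2)
  y <- rep(c(-1, 1), 10)
  X <- cbind(y * 3 + rnorm(20, 0, 0.3), rnorm(20))
  met <- loocv_evaluate(X, y, ids)
  expect_equal(met$accuracy, 1)
  expect_equal(met$auc, 1)
  # bookkeeping identity: metrics recomputed from stored predictions
  expect_equal(met$TP, sum(met$prediction == 1 & y == 1))
  expect_equal(met$accuracy, mean(met$prediction == y))
  expect_equal(met$sensitivity, met$TP / (met$TP + met$FN), tolerance = 1e-12)

  accs <- vapply(1:20, function(r) {
    set.seed(400 + r)
    Xn <- matrix(rnorm(24 * 4), 24, 4)
    loocv_evaluate(Xn, rep(c(-1, 1), 12), rep(sprintf("s%02d", 1:12),
                                              each = 2))$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("subject- and scan-level schemes differ only in the folds", {
  set.seed(3)
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(c(-1, 1), 4)
  ids <- rep(c("a", "b", "c", "d"), each = 2)
  ms <- loocv_evaluate(X, y, ids, scheme = "subject")
  mc <- loocv_evaluate(X, y, scheme = "scan")
  expect_equal(sort(unique(ms$fold)), 1:4)
  expect_equal(sort(unique(mc$fold)), 1:8)
  expect_error(loocv_evaluate(X, y, scheme = "subject"), "subject_ids")
})

test_that("permutation p-values follow their definitions and seed", {
  set.seed(21)
  ids <- rep(sprintf("s%02d", 1:12), each = 2)
  y <- rep(c(-1, 1), 12)
  X <- matrix(rnorm(24 * 6), 24, 6) + 0.9 * y  # clear multi-feature signal
  # study-faithful per-scan randomization: observed beats every null
  p1 <- permutation_test(X, y, ids, B = 99, seed = 7, pairing = "scan")
  expect_equal(p1$p_raw, sum(p1$null_accuracies >= p1$observed_accuracy) / 99)
  expect_equal(p1$p_add_one,
               (sum(p1$null_accuracies >= p1$observed_accuracy) + 1) / 100)
  expect_equal(p1$p_raw, 0)
  expect_equal(p1$p_add_one, 1 / 100)
  p2 <- permutation_test(X, y, ids, B = 99, seed = 7, pairing = "scan")
  expect_identical(p1$null_accuracies, p2$null_accuracies)
  p3 <- permutation_test(X, y, ids, B = 99, seed = 8, pairing = "scan")
  expect_false(identical(p1$null_accuracies, p3$null_accuracies))
  # subject-paired flips preserve the paired design; with few subjects the
  # flip space is small, so its null has a heavier right tail
  p4 <- permutation_test(X, y, ids, B = 50, seed = 1, pairing = "subject")
  expect_length(p4$null_accuracies, 50)
  expect_equal(p4$p_raw,
               mean(p4$null_accuracies >= p4$observed_accuracy))
  expect_error(permutation_test(X, y, ids, B = 0), ">= 1")
})
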
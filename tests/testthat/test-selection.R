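# Paired t screening and the accuracy-driven RFE.

test_that("paired_t_test matches hand computation and edge contracts", {
  r <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$t, 4, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-4, 2), tolerance = 1e-12)
  expect_equal(r$p, 0.0572, tolerance = 1e-3)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_warning(shift <- paired_t_test(c(1, 2, 3), c(2, 3, 4)),
                 "zero variance")
  expect_true(is.nan(shift$p))
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "lengths differ")
})

test_that("stage-1 screening recovers planted regions and respects alpha", {
  # recovery: strongly planted regions survive screening in every replicate
  hits <- vapply(1:20, function(r) {
    cfg <- small_cfg(planted_regions = 1:10, effect_size = 2.0,
                     seed = 300 + r)
    fm <- features_with_cfmt(cfg)$fm
    s1 <- stage1_select(fm, 0.05)
    sum(1:10 %in% s1$regions)
  }, numeric(1))
  expect_gte(mean(hits == 10), 0.95)

  # vanishing alpha empties the set; null cohorts stay far below R
  cfg0 <- small_cfg(effect_size = 0, seed = 31)
  fm0 <- features_with_cfmt(cfg0)$fm
  expect_length(stage1_select(fm0, 1e-12)$regions, 0)
  expect_lt(length(stage1_select(fm0, 0.05)$regions), 0.25 * 60)
  expect_error(stage1_select(feature_matrix(matrix(rnorm(12), 6, 2),
                                            rep(c("a", "b", "c"), each = 2),
                                            rep(c("pre", "post"), 3)), 0.05),
               "fewer than 3")
})

# 8 samples in 2 informative dimensions that only separate jointly, plus a
# pure-noise third feature: the constructed batch-RFE example
rfe_example <- function() {
  x12 <- rbind(c(0, 1.1), c(1.1, 0), c(0.1, 1.2), c(1.2, 0.1),
               c(0, -1.1), c(-1.1, 0), c(-0.1, -1.2), c(-1.2, -0.1))
  y <- c(1, 1, 1, 1, -1, -1, -1, -1)
  noise <- c(0.3, -0.2, 0.25, -0.31, 0.28, -0.27, 0.33, -0.24)
  list(x = cbind(x12, noise), y = y, fold = 1:8)
}

test_that("RFE removes the noise feature and keeps the joint separators", {
  ex <- rfe_example()
  fm <- feature_matrix(ex$x, rep(sprintf("s%d", 1:4), each = 2),
                       rep(c("pre", "post"), 4))
  fm$labels <- ex$y  # constructed labels; pairing irrelevant at scan level
  sel <- rfe_select(fm, scheme = "scan")
  expect_identical(sel$stage2_regions, c(1L, 2L))
  expect_equal(sel$accuracy_trace[1], 1.0)
  expect_identical(unlist(sel$removed_per_round), 3L)
  expect_equal(sel$final_accuracy, 1.0)
})

test_that("single-feature input is returned unchanged", {
  set.seed(13)
  fm <- feature_matrix(matrix(c(rnorm(4, -1), rnorm(4, 1))[sample(8)], 8, 1),
                       rep(sprintf("s%d", 1:4), each = 2),
                       rep(c("pre", "post"), 4))
  sel <- rfe_select(fm, scheme = "scan")
  expect_identical(sel$stage2_regions, 1L)
  expect_length(sel$accuracy_trace, 1)
})

test_that("RFE equals the brute-force greedy simulator on small problems", {
  set.seed(77)
  for (i in 1:10) {
    n <- 2 * sample(3:6, 1)
    p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c(-1, 1), n / 2)
    x[, 1] <- x[, 1] + 0.8 * y  # some signal so accuracies vary
    ids <- rep(sprintf("s%d", seq_len(n / 2)), each = 2)
    fm <- feature_matrix(x, ids, rep(c("pre", "post"), n / 2))
    fm$labels <- y
    sel <- rfe_select(fm, scheme = "scan")
    orc <- oracle_rfe(x, y, seq_len(n), C = 1)
    expect_identical(sort(sel$stage2_regions), sort(orc$final))
    expect_equal(sel$accuracy_trace, orc$trace, tolerance = 1e-12)
  }
})

test_that("RFE trace is non-decreasing and the result deterministic", {
  cfg <- small_cfg(planted_regions = 1:6, effect_size = 1.5, seed = 55)
  env <- features_with_cfmt(cfg)
  s1 <- stage1_select(env$fm, 0.05)
  fm2 <- rescale_features(regress_out_confound(
    subset_regions(env$fm, s1$regions), env$cfmt))
  sel1 <- rfe_select(fm2)
  sel2 <- rfe_select(fm2)
  expect_identical(sel1, sel2)
  expect_true(all(diff(sel1$accuracy_trace) >= -1e-12))
  expect_gte(sel1$final_accuracy, sel1$accuracy_trace[1])
  expect_true(all(sel1$stage2_regions %in% s1$regions))
})

test_that("non-binary labels are rejected", {
  fm <- feature_matrix(matrix(rnorm(8), 4, 2), c("a", "a", "b", "b"),
                       c("pre", "post", "pre", "post"))
  fm$labels <- c(0, 1, 2, 1)
  expect_error(rfe_select(fm), "\\+1 and -1")
})
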
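# The synthetic cohort generator: contracts, determinism, and Monte-Carlo
# calibration of the planted effect.

test_that("generate_atlas covers every label and is deterministic", {
  cfg <- synthetic_config(n_subjects = 2, n_regions = 4,
                          volume_dims = c(4, 4, 1), n_volumes = 16, seed = 1)
  at <- generate_atlas(cfg)
  expect_setequal(unique(at$labels[at$labels > 0]), 1:4)
  expect_identical(generate_atlas(cfg)$labels, at$labels)

  cfg246 <- synthetic_config(n_regions = 246, volume_dims = c(18, 18, 12))
  a246 <- generate_atlas(cfg246)
  sizes <- tabulate(a246$labels[a246$labels > 0], 246)
  expect_true(all(sizes >= 1))
  expect_equal(sum(sizes), sum(a246$labels > 0))

  expect_error(generate_atlas(synthetic_config(n_regions = 50,
                                               volume_dims = c(3, 3, 3))),
               "too small")
})

test_that("subject images are deterministic and reject bad conditions", {
  cfg <- tiny_cfg(seed = 3)
  at <- generate_atlas(cfg)
  i1 <- generate_subject_image(cfg, at, 2, "post")
  i2 <- generate_subject_image(cfg, at, 2, "post")
  expect_identical(i1$data, i2$data)
  i3 <- generate_subject_image(cfg, at, 2, "pre")
  expect_false(identical(i1$data, i3$data))
  expect_error(generate_subject_image(cfg, at, 2, "during"), "condition")
})

test_that("cohort cardinality, truth record, and bit-reproducibility", {
  cfg <- tiny_cfg(planted_regions = c(2L, 9L), effect_size = 1,
                  high_motion_subjects = 4L, seed = 11)
  co <- generate_cohort(cfg)
  expect_length(co$images, 20)
  expect_length(co$motion, 20)
  expect_equal(nrow(co$behavior), 10)
  expect_identical(co$truth$planted_regions, c(2L, 9L))
  expect_identical(co$truth$high_motion_subjects, 4L)
  co2 <- generate_cohort(cfg)
  expect_identical(co$images[["s07_pre"]]$data, co2$images[["s07_pre"]]$data)
  expect_identical(co$behavior, co2$behavior)
  expect_identical(co$motion, co2$motion)
})

test_that("injected high-motion subjects are exactly the excluded ones", {
  cfg <- synthetic_config(n_subjects = 32, n_regions = 20,
                          volume_dims = c(8, 8, 6), n_volumes = 48,
                          high_motion_subjects = c(5L, 21L), seed = 2)
  motion <- list()
  for (s in 1:32) for (cond in c("pre", "post"))
    motion[[sprintf("s%02d_%s", s, cond)]] <- generate_motion(cfg, s, cond)
  qc <- exclude_high_motion(motion, threshold = 0.2)
  expect_identical(qc$excluded_subjects, c(5L, 21L))
  expect_length(qc$retained_subjects, 30)
})

test_that("behavioral table matches the emulated study profile", {
  cfg <- synthetic_config(n_subjects = 30, n_regions = 10,
                          volume_dims = c(6, 6, 4), n_volumes = 32, seed = 9)
  b <- generate_behavior(cfg)
  expect_true(all(b$ret_pre >= 0 & b$ret_pre <= 1))
  expect_true(all(b$ret_post >= 0 & b$ret_post <= 1))
  expect_true(all(b$ret_rt_pre > 0 & b$ret_rt_post > 0))
  expect_true(all(b$cfmt_pre >= 0 & b$cfmt_pre <= 72))
  # RET improves strongly; CFMT essentially unchanged
  expect_gt(mean(b$ret_post - b$ret_pre), 0.15)
  expect_lt(abs(mean(b$cfmt_post - b$cfmt_pre)), 2)
})

test_that("null generator plants no region-wise effect (Monte Carlo)", {
  cfg <- synthetic_config(n_subjects = 200, n_regions = 40,
                          volume_dims = c(10, 10, 6), n_volumes = 64,
                          effect_size = 0, seed = 11)
  at <- generate_atlas(cfg)
  d <- matrix(NA_real_, cfg$n_subjects, cfg$n_regions)
  for (s in seq_len(cfg$n_subjects)) {
    rv <- vapply(c("pre", "post"), function(cond) {
      img <- generate_subject_image(cfg, at, s, cond)
      region_average(standardize_alff(compute_voxel_alff(img)), at)
    }, numeric(cfg$n_regions))
    d[s, ] <- rv[, "post"] - rv[, "pre"]
  }
  se <- apply(d, 2, stats::sd) / sqrt(nrow(d))
  expect_true(all(abs(colMeans(d)) < 3 * se))
})

test_that("planted amplitude change hits the requested effect size", {
  cfg <- synthetic_config(n_subjects = 200, n_regions = 246,
                          volume_dims = c(12, 12, 8), n_volumes = 96,
                          planted_regions = 1:10, effect_size = 2.0,
                          seed = 5)
  at <- generate_atlas(cfg)
  d <- matrix(NA_real_, cfg$n_subjects, 10)
  for (s in seq_len(cfg$n_subjects)) {
    rv <- vapply(c("pre", "post"), function(cond) {
      img <- generate_subject_image(cfg, at, s, cond)
      region_average(standardize_alff(compute_voxel_alff(img)), at)
    }, numeric(cfg$n_regions))
    d[s, ] <- (rv[, "post"] - rv[, "pre"])[1:10]
  }
  emp_d <- colMeans(d) / apply(d, 2, stats::sd)
  expect_true(all(abs(emp_d - 2.0) < 0.3))
  expect_lt(abs(mean(emp_d) - 2.0), 0.3)
})

test_that("written cohorts roundtrip through the standard formats", {
  cfg <- synthetic_config(n_subjects = 2, n_regions = 5,
                          volume_dims = c(6, 6, 4), n_volumes = 24, seed = 4)
  co <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort_dir(dir)
  expect_identical(back$atlas$labels, co$atlas$labels)
  expect_equal(back$images[["s01_pre"]]$data, co$images[["s01_pre"]]$data)
  expect_equal(unname(back$motion[["s02_post"]]), unname(co$motion[["s02_post"]]),
               tolerance = 1e-8)
  expect_equal(back$behavior$ret_post, co$behavior$ret_post)
  expect_length(back$truth$planted_regions, 0)
})
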
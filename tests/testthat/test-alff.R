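# Detrending, framewise displacement, voxel/region ALFF.

test_that("linear_detrend removes lines exactly and matches lm residuals", {
  expect_equal(linear_detrend(c(1, 2, 3, 4)), rep(0, 4))
  expect_equal(linear_detrend(rep(5, 10)), rep(0, 10))
  y <- c(1, 0, 1, 0)
  expect_equal(linear_detrend(y),
               unname(stats::residuals(stats::lm(y ~ seq_along(y)))),
               tolerance = 1e-12)
  # matrix form agrees with column-wise application
  set.seed(2)
  m <- matrix(rnorm(60), 20, 3)
  dm <- linear_detrend(m)
  expect_equal(dm[, 2], linear_detrend(m[, 2]))
  x <- seq_len(20)
  expect_lt(max(abs(colSums(dm))), 1e-10)
  expect_lt(max(abs(colSums(dm * x))), 1e-9)  # orthogonal to the trend
  expect_error(linear_detrend(c(1, 2)), "at least 3")
})

test_that("framewise displacement follows the Power definition", {
  mp0 <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(mp0), rep(0, 10))
  mp <- matrix(0, 3, 6)
  mp[2, ] <- c(0.1, 0.1, 0.1, 0.001, 0, 0)
  fd <- framewise_displacement(mp, head_radius = 50)
  expect_equal(fd[1], 0)
  expect_equal(fd[2], 0.3 + 50 * 0.001)
  expect_equal(fd[3], 0.3 + 50 * 0.001)  # moving back costs the same
  expect_error(framewise_displacement(matrix(0, 5, 4)), "6 columns")
  expect_error(framewise_displacement(matrix(0, 1, 6)), "at least 2")
})

test_that("high-motion exclusion handles boundary thresholds", {
  cfg <- tiny_cfg(high_motion_subjects = 3L, seed = 8)
  motion <- list()
  for (s in 1:4) for (cond in c("pre", "post"))
    motion[[sprintf("s%02d_%s", s, cond)]] <- generate_motion(cfg, s, cond)
  expect_length(exclude_high_motion(motion, Inf)$excluded_subjects, 0)
  all_out <- exclude_high_motion(motion, -1)
  expect_length(all_out$retained_subjects, 0)
  expect_length(all_out$excluded_subjects, 4)
  qc <- exclude_high_motion(motion, 0.2)
  expect_identical(qc$excluded_subjects, 3L)
  expect_true(all(qc$log$fd[qc$log$subject == 3] > 0.2))
})

test_that("voxel ALFF has the closed form for pure sinusoids", {
  n <- 200; tr <- 2
  t <- 0:(n - 1)
  sine <- 2 * sin(2 * pi * 0.05 * t * tr)  # bin 20 of 29 in-band bins
  dat <- array(0, c(1, 1, 1, n)); dat[1, 1, 1, ] <- sine
  img <- bold_image(dat, tr)
  # the operation takes detrended input; the sinusoid stands in for it
  m <- compute_voxel_alff(img, c(0.01, 0.08), detrend = FALSE)
  expect_equal(m$values[1, 1, 1], 2 / 29, tolerance = 1e-10)
  # constant voxel: zero after detrending
  dat[1, 1, 1, ] <- 7
  expect_equal(compute_voxel_alff(bold_image(dat, tr))$values[1, 1, 1], 0,
               tolerance = 1e-12)
  # linearity: scaling the series scales ALFF
  dat[1, 1, 1, ] <- sine * 3.5
  expect_equal(compute_voxel_alff(bold_image(dat, tr),
                                  detrend = FALSE)$values[1, 1, 1],
               3.5 * 2 / 29, tolerance = 1e-9)
  expect_error(compute_voxel_alff(img, c(0.01, 0.3)), "Nyquist")
  expect_error(compute_voxel_alff(img, c(0.08, 0.01)), "increasing")
})

test_that("voxel ALFF matches the literal spectral oracle", {
  set.seed(10)
  n <- 120; tr <- 2
  for (i in 1:100) {
    ts <- rnorm(n) + cumsum(rnorm(n, 0, 0.05))
    dat <- array(ts, c(1, 1, 1, n))
    got <- compute_voxel_alff(bold_image(dat, tr))$values[1, 1, 1]
    expect_equal(got, oracle_alff(ts, tr), tolerance = 1e-10)
  }
})

test_that("band bookkeeping: bins grow with the band and full >= sub-band", {
  n <- 160; tr <- 2
  bins <- function(b) length(alffsvm:::.band_bins(n, tr, b))
  expect_true(bins(c(0.01, 0.08)) <= bins(c(0.01, 0.12)))
  expect_true(bins(c(0.01, 0.08)) <= bins(c(0.005, 0.08)))
  set.seed(3)
  ts <- linear_detrend(rnorm(n))
  dat <- array(ts, c(1, 1, 1, n))
  img <- bold_image(dat, tr)
  full_band <- c(1 / (n * tr), 1 / (2 * tr))
  a_full <- compute_voxel_alff(img, full_band, detrend = FALSE)$values[1]
  a_sub <- compute_voxel_alff(img, c(0.01, 0.08), detrend = FALSE)$values[1]
  k_full <- bins(full_band); k_sub <- bins(c(0.01, 0.08))
  # sub-band amplitude sum cannot exceed the full-band amplitude sum
  expect_gte(a_full * k_full, a_sub * k_sub - 1e-12)
})

test_that("white-noise ALFF scales with the noise SD", {
  set.seed(4)
  n <- 100
  alff_of <- function(sigma) {
    mean(replicate(60, {
      dat <- array(rnorm(n, sd = sigma), c(1, 1, 1, n))
      compute_voxel_alff(bold_image(dat, 2))$values[1]
    }))
  }
  expect_equal(alff_of(2) / alff_of(1), 2, tolerance = 0.15)
})

test_that("prefiltering through the same rectangular band changes nothing", {
  set.seed(6)
  dat <- array(rnorm(2 * 2 * 1 * 80), c(2, 2, 1, 80))
  img <- bold_image(dat, 2)
  a <- compute_voxel_alff(img, prefilter = FALSE)
  b <- compute_voxel_alff(img, prefilter = TRUE)
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("standardization yields unit in-mask mean and is idempotent", {
  vals <- array(0, c(2, 1, 1, 20))
  vals[1, 1, 1, ] <- sin(2 * pi * 0.05 * (0:19) * 2)      # some power
  vals[2, 1, 1, ] <- 3 * sin(2 * pi * 0.05 * (0:19) * 2)  # three times more
  m <- compute_voxel_alff(bold_image(vals, 2), c(0.01, 0.1))
  # two-voxel map with 1:3 ratio standardizes to 0.5 / 1.5
  s <- standardize_alff(m)
  expect_equal(as.numeric(s$values[s$mask] / sum(s$values[s$mask]) * 2),
               c(0.5, 1.5), tolerance = 1e-8)
  expect_equal(mean(s$values[s$mask]), 1, tolerance = 1e-9)
  expect_equal(standardize_alff(s)$values, s$values, tolerance = 1e-12)
  bad <- m; bad$values[] <- 0
  expect_error(standardize_alff(bad), "in-mask mean")
})

test_that("region averaging respects the parcellation", {
  cfg <- tiny_cfg(seed = 5)
  at <- generate_atlas(cfg)
  img <- generate_subject_image(cfg, at, 1, "pre")
  m <- standardize_alff(compute_voxel_alff(img))
  v <- region_average(m, at)
  expect_length(v, cfg$n_regions)
  expect_false(anyNA(v))
  # single-region atlas over the same mask: the global mean, exactly 1
  one <- parcellation_atlas(array(as.integer(at$labels > 0), dim(at$labels)))
  expect_equal(unname(region_average(m, one)), 1, tolerance = 1e-9)
  # hand-check one region against a direct mean
  r <- 7
  expect_equal(unname(v[r]), mean(m$values[at$labels == r]))
  wrong <- parcellation_atlas(array(1L, c(2, 2, 2)))
  expect_error(region_average(m, wrong), "dimensions")
  mm <- m
  mm$standardized <- FALSE
  expect_warning(region_average(mm, at), "non-standardized")
})
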
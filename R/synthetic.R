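# Synthetic paired resting-state cohort with known planted effects.
#
# The generator emulates the study design the pipeline is built for: ~30
# subjects scanned pre and post training, TR = 2 s, 175 retained volumes,
# band-limited (0.01-0.08 Hz) spontaneous oscillations riding on AR(1) noise
# and a slow drift, a 246-region parcellation, per-scan 6-parameter motion
# traces, and behavioral scores (CFMT stable, RET improving). A configurable
# subset of regions carries a condition-dependent amplitude change calibrated
# so the paired (post - pre) region ALFF difference has a requested
# standardized effect size.

#' Configuration of the synthetic paired cohort
#'
#' @param n_subjects number of subjects (paired pre/post scans each).
#' @param n_regions number of atlas regions.
#' @param volume_dims integer vector of 3 voxel-grid dimensions.
#' @param n_volumes retained volumes per scan (>= 16).
#' @param tr repetition time, seconds.
#' @param planted_regions region labels carrying the post-training amplitude
#'   change; subset of `1:n_regions`.
#' @param effect_size target standardized paired effect (Cohen's d of
#'   post - pre region ALFF) in planted regions; >= 0.
#' @param osc_band frequency interval (Hz) of the planted oscillation;
#'   also the band the downstream ALFF analysis is expected to use.
#' @param noise_ar1 lag-1 autocorrelation of the voxel noise, in [0, 1).
#' @param noise_sd marginal standard deviation of the voxel noise.
#' @param osc_amp baseline per-bin oscillation amplitude (arbitrary BOLD
#'   units); every in-band DFT bin carries this amplitude, so a region's
#'   oscillation contributes exactly its amplitude to region ALFF.
#' @param subject_sd between-subject SD of the subject-by-region amplitude
#'   profile (fractional); shared across conditions, it induces the pre/post
#'   correlation a paired design relies on.
#' @param scan_jitter_sd session-to-session fractional amplitude jitter.
#' @param cfmt_mean_sd length-2 vector: mean and SD of the CFMT score.
#' @param cfmt_coupling correlation in [0, 1) between the CFMT score and the
#'   subject amplitude profile in `cfmt_coupled_regions` (0 = no coupling).
#' @param cfmt_coupled_regions region labels coupled to CFMT.
#' @param high_motion_subjects subject indices generated with exaggerated
#'   head motion (mean Power FD well above 0.2 mm).
#' @param seed integer seed; identical configurations regenerate identical
#'   cohorts bit for bit.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 30L, n_regions = 246L,
                             volume_dims = c(18L, 18L, 12L),
                             n_volumes = 175L, tr = 2.0,
                             planted_regions = integer(0),
                             effect_size = 0,
                             osc_band = c(0.01, 0.08),
                             noise_ar1 = 0.4, noise_sd = 1.0,
                             osc_amp = 0.5, subject_sd = 0.35,
                             scan_jitter_sd = 0.1,
                             cfmt_mean_sd = c(56.9, 4.29),
                             cfmt_coupling = 0,
                             cfmt_coupled_regions = integer(0),
                             high_motion_subjects = integer(0),
                             seed = 1L) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_regions = check_count(n_regions, "n_regions"),
    volume_dims = vapply(volume_dims, check_count, integer(1),
                         what = "volume_dims"),
    n_volumes = check_count(n_volumes, "n_volumes", min = 16L),
    tr = check_number(tr, "tr", lower = 0, strict_lower = TRUE),
    planted_regions = as.integer(planted_regions),
    effect_size = check_number(effect_size, "effect_size", lower = 0),
    osc_band = as.numeric(osc_band),
    noise_ar1 = check_number(noise_ar1, "noise_ar1", lower = 0, upper = 0.999),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0,
                            strict_lower = TRUE),
    osc_amp = check_number(osc_amp, "osc_amp", lower = 0, strict_lower = TRUE),
    subject_sd = check_number(subject_sd, "subject_sd", lower = 0),
    scan_jitter_sd = check_number(scan_jitter_sd, "scan_jitter_sd", lower = 0),
    cfmt_mean_sd = as.numeric(cfmt_mean_sd),
    cfmt_coupling = check_number(cfmt_coupling, "cfmt_coupling",
                                 lower = 0, upper = 0.99),
    cfmt_coupled_regions = as.integer(cfmt_coupled_regions),
    high_motion_subjects = as.integer(high_motion_subjects),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$volume_dims) != 3L) stop_arg("volume_dims must have length 3")
  if (length(cfg$osc_band) != 2L || cfg$osc_band[1] <= 0 ||
      cfg$osc_band[2] <= cfg$osc_band[1])
    stop_arg("osc_band must be an increasing positive frequency interval")
  if (cfg$osc_band[2] > 1 / (2 * cfg$tr))
    stop_arg("osc_band exceeds the Nyquist frequency 1/(2*tr)")
  if (length(cfg$planted_regions) &&
      (any(cfg$planted_regions < 1L) ||
       any(cfg$planted_regions > cfg$n_regions)))
    stop_arg("planted_regions must lie in 1..n_regions")
  if (anyDuplicated(cfg$planted_regions))
    stop_arg("planted_regions must be distinct")
  structure(cfg, class = "synthetic_config")
}

# deterministic per-subject / per-scan RNG streams (kept below 2^31)
.subject_seed <- function(cfg, subject_id)
  (cfg$seed * 1000003 + subject_id * 97) %% 2147483629

.scan_seed <- function(cfg, subject_id, condition)
  (.subject_seed(cfg, subject_id) +
     524287 * (1L + as.integer(condition == "post"))) %% 2147483629

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# ellipsoidal brain mask inscribed in the voxel grid
.ellipsoid_mask <- function(dims) {
  ctr <- (dims + 1) / 2
  rad <- dims / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
    ((g$z - ctr[3]) / rad[3])^2
  array(d2 <= 1, dim = dims)
}

#' Generate a synthetic parcellation atlas
#'
#' Voxels inside an ellipsoidal brain mask are partitioned into
#' `n_regions` Voronoi cells around seeded center voxels, so every region
#' label 1..n_regions occupies at least one voxel; 0 marks background.
#'
#' @param config a [synthetic_config()].
#' @return a [parcellation_atlas()].
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dims <- config$volume_dims
  mask <- .ellipsoid_mask(dims)
  idx <- which(mask)
  if (config$n_regions > length(idx))
    stop_arg("volume_dims too small: mask has ", length(idx),
             " voxels for ", config$n_regions, " regions")
  coords <- which(mask, arr.ind = TRUE)
  centers <- .with_seed(config$seed, sample(nrow(coords), config$n_regions))
  cc <- coords[centers, , drop = FALSE]
  # nearest-center assignment; ties resolved to the lowest region label
  lab <- integer(nrow(coords))
  for (v in seq_len(nrow(coords))) {
    d2 <- (coords[v, 1] - cc[, 1])^2 + (coords[v, 2] - cc[, 2])^2 +
      (coords[v, 3] - cc[, 3])^2
    lab[v] <- which.min(d2)
  }
  lab[centers] <- seq_len(config$n_regions)  # centers keep their own label
  vol <- array(0L, dim = dims)
  vol[idx] <- lab
  parcellation_atlas(vol)
}

# AR(1) spectral density at frequency f (cycles/sample) for unit-lag
# autocorrelation a and innovation variance s2e
.ar1_spec <- function(f, a, s2e) s2e / (1 - 2 * a * cos(2 * pi * f) + a^2)

# in-band DFT bin indices k (1..floor(N/2)) for series length N, sampling tr
.band_bins <- function(n, tr, band) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  k[f >= band[1] & f <= band[2]]
}

# Analytic calibration of the post-condition amplitude multiplier (1 + delta)
# so the paired region-ALFF difference has standardized effect ~ effect_size.
# The paired difference d_r = ALFF_post - ALFF_pre has
#   mean  = osc_amp * delta
#   var   = osc_amp^2 * (delta^2 rho^2 + tau^2 (1 + (1+delta)^2)(1 + rho^2))
#           + 2 * v_nf / V_r
# where v_nf is the per-voxel in-band amplitude variance contributed by the
# noise spectrum (signal-dominated regime) and V_r the region's voxel count.
.calibrate_delta <- function(config, region_size) {
  e <- config$effect_size
  if (e == 0) return(rep(0, length(region_size)))
  n <- config$n_volumes
  bins <- .band_bins(n, config$tr, config$osc_band)
  if (!length(bins)) stop_arg("osc_band contains no DFT bin at this length")
  s2e <- config$noise_sd^2 * (1 - config$noise_ar1^2)
  spec <- .ar1_spec(bins / n, config$noise_ar1, s2e)
  v_vox <- sum(2 * spec / n) / length(bins)^2
  rho <- config$subject_sd
  tau <- config$scan_jitter_sd
  a0 <- config$osc_amp
  vapply(region_size, function(V) {
    f <- function(delta) {
      v <- a0^2 * (delta^2 * rho^2 +
                     tau^2 * (1 + (1 + delta)^2) * (1 + rho^2)) +
        2 * v_vox / max(V, 1)
      a0 * delta / sqrt(v) - e
    }
    if (f(100) < 0) return(100)  # unreachable effect; saturate
    stats::uniroot(f, c(1e-9, 100), tol = 1e-10)$root
  }, numeric(1))
}

# subject-level amplitude profile and CFMT latent, shared across conditions
.subject_profile <- function(config, subject_id) {
  .with_seed(.subject_seed(config, subject_id), {
    cfmt_z <- rnorm(1)
    z <- rnorm(config$n_regions)
    g <- 1 + config$subject_sd * z
    if (config$cfmt_coupling > 0 && length(config$cfmt_coupled_regions)) {
      cc <- config$cfmt_coupling
      r <- config$cfmt_coupled_regions
      g[r] <- 1 + config$subject_sd * (cc * cfmt_z + sqrt(1 - cc^2) * z[r])
    }
    list(cfmt_z = cfmt_z, gain = pmax(g, 0.05))
  })
}

#' Generate one synthetic BOLD-like scan
#'
#' Each in-mask voxel time series is a slow linear drift plus AR(1) Gaussian
#' noise plus a random-phase oscillation built from sinusoids at the DFT
#' frequencies inside `osc_band`. The oscillation amplitude is shared within
#' a region and factorizes into a subject-level profile (common to both
#' conditions), a session jitter, and -- for planted regions in the post
#' condition -- a calibrated amplitude increase.
#'
#' @param config a [synthetic_config()].
#' @param atlas the cohort's [parcellation_atlas()] (see [generate_atlas()]).
#' @param subject_id subject index in `1:n_subjects`.
#' @param condition `"pre"` or `"post"`.
#' @return a [bold_image()].
#' @export
generate_subject_image <- function(config, atlas, subject_id, condition) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(atlas, "parcellation_atlas"))
  if (!condition %in% c("pre", "post"))
    stop_arg("condition must be 'pre' or 'post', got '", condition, "'")
  subject_id <- check_count(subject_id, "subject_id")

  labels <- atlas$labels
  mask <- labels > 0L
  vox_region <- labels[mask]
  n_vox <- sum(mask)
  n <- config$n_volumes
  bins <- .band_bins(n, config$tr, config$osc_band)
  if (!length(bins)) stop_arg("osc_band contains no DFT bin at this length")

  region_size <- tabulate(vox_region, nbins = config$n_regions)
  delta <- rep(0, config$n_regions)
  if (length(config$planted_regions) && config$effect_size > 0)
    delta[config$planted_regions] <-
      .calibrate_delta(config, region_size[config$planted_regions])

  prof <- .subject_profile(config, subject_id)
  .with_seed(.scan_seed(config, subject_id, condition), {
    eta <- rnorm(config$n_regions, 0, config$scan_jitter_sd)
    amp_region <- config$osc_amp * prof$gain * (1 + eta)
    if (condition == "post") amp_region <- amp_region * (1 + delta)
    amp_region <- pmax(amp_region, 0)

    # random-phase in-band oscillation: every in-band bin carries the region
    # amplitude, so the oscillation's contribution to region ALFF is exact
    phase <- matrix(runif(n_vox * length(bins), 0, 2 * pi), n_vox)
    basis <- exp(1i * 2 * pi * outer(bins, 0:(n - 1)) / n)  # K x N
    osc <- Re((amp_region[vox_region] * exp(1i * phase)) %*% basis)

    # AR(1) noise, marginal sd = noise_sd
    innov <- matrix(rnorm(n * n_vox,
                          sd = config$noise_sd * sqrt(1 - config$noise_ar1^2)),
                    n, n_vox)
    noise <- stats::filter(innov, config$noise_ar1, method = "recursive")
    noise <- t(matrix(as.numeric(noise), n, n_vox))

    drift <- outer(rnorm(n_vox, 0, 0.5), seq(-1, 1, length.out = n))

    ts <- 100 + osc + noise + drift
    dat <- array(0, dim = c(dim(labels), n))
    flat <- matrix(dat, ncol = n)
    flat[which(mask), ] <- ts
    bold_image(array(flat, dim = c(dim(labels), n)), tr = config$tr,
               mask = mask)
  })
}

#' Generate one synthetic 6-parameter motion trace
#'
#' Translations (mm) and rotations (radians) follow independent random walks
#' scaled so that a compliant subject has mean Power FD around 0.1 mm;
#' subjects listed in `config$high_motion_subjects` are scaled up to exceed
#' the conventional 0.2 mm exclusion threshold.
#'
#' @inheritParams generate_subject_image
#' @return a numeric matrix with `n_volumes` rows and 6 columns
#'   (tx, ty, tz in mm; rx, ry, rz in radians).
#' @export
generate_motion <- function(config, subject_id, condition) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!condition %in% c("pre", "post"))
    stop_arg("condition must be 'pre' or 'post', got '", condition, "'")
  scale <- if (subject_id %in% config$high_motion_subjects) 3.5 else 1
  .with_seed(.scan_seed(config, subject_id, condition) + 13L, {
    n <- config$n_volumes
    steps <- cbind(matrix(rnorm(3 * n, 0, 0.02), n),    # translations, mm
                   matrix(rnorm(3 * n, 0, 4e-4), n))    # rotations, rad
    mp <- apply(steps * scale, 2, cumsum)
    colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    mp
  })
}

#' Generate the behavioral score table
#'
#' CFMT is drawn once per subject and held constant up to small jitter
#' (face expertise does not change with radiological training); RET accuracy
#' improves and RET response time shortens post-training.
#'
#' @param config a [synthetic_config()].
#' @return a data.frame with one row per subject: `subject`, `cfmt_pre`,
#'   `cfmt_post`, `ret_pre`, `ret_post`, `ret_rt_pre`, `ret_rt_post`.
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ns <- config$n_subjects
  cfmt_z <- vapply(seq_len(ns),
                   function(s) .subject_profile(config, s)$cfmt_z, numeric(1))
  .with_seed(config$seed + 777L, {
    cfmt_pre <- round(config$cfmt_mean_sd[1] + config$cfmt_mean_sd[2] * cfmt_z)
    cfmt_pre <- pmin(pmax(cfmt_pre, 0), 72)
    cfmt_post <- pmin(pmax(round(cfmt_pre + rnorm(ns, 0.4, 1.2)), 0), 72)
    ret_pre <- pmin(pmax(rnorm(ns, 0.61, 0.05), 0), 1)
    ret_post <- pmin(pmax(rnorm(ns, 0.84, 0.04), 0), 1)
    rt_pre <- pmax(rnorm(ns, 3.08, 0.30), 0.5)
    rt_post <- pmax(rnorm(ns, 2.53, 0.34), 0.5)
    data.frame(subject = seq_len(ns),
               cfmt_pre = cfmt_pre, cfmt_post = cfmt_post,
               ret_pre = ret_pre, ret_post = ret_post,
               ret_rt_pre = rt_pre, ret_rt_post = rt_post)
  })
}

#' Generate the full synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @param images keep the generated [bold_image()] objects in the returned
#'   cohort (default). Set to `FALSE` for large configurations where only
#'   derived quantities are needed; images can always be regenerated
#'   deterministically with [generate_subject_image()].
#' @return an object of class `alff_cohort`: list with `config`, `atlas`,
#'   `images` (named `s<ID>_<condition>`), `motion` (same names),
#'   `behavior` (data.frame), and `truth` (planted regions, effect size,
#'   calibrated amplitude deltas, high-motion subjects).
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  atlas <- generate_atlas(config)
  scan_names <- as.vector(t(outer(seq_len(config$n_subjects),
                                  c("pre", "post"),
                                  function(s, c) sprintf("s%02d_%s", s, c))))
  motion <- list()
  imgs <- if (images) list() else NULL
  for (s in seq_len(config$n_subjects)) {
    for (cond in c("pre", "post")) {
      nm <- sprintf("s%02d_%s", s, cond)
      motion[[nm]] <- generate_motion(config, s, cond)
      if (images) imgs[[nm]] <- generate_subject_image(config, atlas, s, cond)
    }
  }
  region_size <- tabulate(atlas$labels[atlas$labels > 0L],
                          nbins = config$n_regions)
  delta <- rep(0, config$n_regions)
  if (length(config$planted_regions) && config$effect_size > 0)
    delta[config$planted_regions] <-
      .calibrate_delta(config, region_size[config$planted_regions])
  structure(list(
    config = config,
    atlas = atlas,
    images = imgs,
    motion = motion,
    behavior = generate_behavior(config),
    truth = list(planted_regions = config$planted_regions,
                 effect_size = config$effect_size,
                 amplitude_delta = delta,
                 high_motion_subjects = config$high_motion_subjects,
                 seed = config$seed),
    scan_names = scan_names
  ), class = "alff_cohort")
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Images and atlas as NIfTI, motion as 6-column whitespace-delimited text,
#' behavior as CSV, and the truth record as JSON.
#'
#' @param cohort an `alff_cohort` (must retain its images).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "alff_cohort"))
  if (is.null(cohort$images))
    stop_arg("cohort was generated with images = FALSE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(cohort$atlas$labels, file.path(dir, "atlas.nii"), datatype = 8L)
  for (nm in names(cohort$images)) {
    write_nifti(cohort$images[[nm]]$data,
                file.path(dir, paste0(nm, "_bold.nii")),
                tr = cohort$images[[nm]]$tr, datatype = 64L)
    write_motion(cohort$motion[[nm]], file.path(dir, paste0(nm, "_motion.txt")))
  }
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
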
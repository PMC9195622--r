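# Voxel- and region-wise ALFF from 4D BOLD-like volumes.
#
# ALFF is the mean of the square-root power spectrum (amplitude spectrum) of
# a voxel's detrended time series over the low-frequency band, here with the
# convention amplitude(k) = 2|X_k|/N so a unit sinusoid at a DFT frequency
# has amplitude 1. Any fixed spectral scaling cancels after whole-brain
# standardization; this one makes closed-form tests readable.

#' 4D BOLD-like image container
#'
#' @param data 4D numeric array (x, y, z, t) with t >= 16.
#' @param tr repetition time (sampling interval) in seconds.
#' @param mask 3D logical array of in-brain voxels; defaults to all voxels.
#' @return object of class `bold_image`.
#' @export
bold_image <- function(data, tr, mask = NULL) {
  if (length(dim(data)) != 4L) stop_arg("data must be a 4D array")
  if (dim(data)[4] < 16L) stop_arg("need at least 16 volumes")
  tr <- check_number(tr, "tr", lower = 0, strict_lower = TRUE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3]))
    stop_arg("mask dimensions must match the spatial dimensions of data")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop_arg("mask is empty")
  structure(list(data = data, tr = tr, mask = mask), class = "bold_image")
}

#' Integer-labeled parcellation atlas
#'
#' @param labels 3D array of non-negative integers; 0 is background, regions
#'   are labeled 1..R with every label in that range present.
#' @return object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels) {
  if (length(dim(labels)) != 3L) stop_arg("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop_arg("labels must be non-negative")
  r <- max(labels)
  if (r < 1L) stop_arg("atlas has no regions")
  present <- tabulate(labels[labels > 0L], nbins = r) > 0L
  if (!all(present))
    stop_arg("missing region labels: ",
             paste(which(!present), collapse = ", "))
  structure(list(labels = labels, n_regions = r),
            class = "parcellation_atlas")
}

#' Remove the least-squares linear trend (and mean) from a series
#'
#' @param ts numeric vector, length >= 3, or a matrix with series in columns.
#' @return detrended series with zero mean and zero least-squares slope.
#' @export
linear_detrend <- function(ts) {
  if (is.matrix(ts)) {
    n <- nrow(ts)
    if (n < 3L) stop_arg("need at least 3 time points to detrend")
    x <- seq_len(n) - (n + 1) / 2
    slope <- crossprod(x, ts) / sum(x^2)
    return(ts - rep(colMeans(ts), each = n) - outer(x, drop(slope)))
  }
  if (length(ts) < 3L) stop_arg("need at least 3 time points to detrend")
  drop(linear_detrend(matrix(ts, ncol = 1)))
}

#' Power framewise displacement from 6 rigid-body motion parameters
#'
#' FD(1) = 0 and FD(i) is the sum of absolute backward differences of the
#' three translations (mm) plus `head_radius` times the summed absolute
#' rotation differences (radians converted to arc length).
#'
#' @param mp numeric matrix, one row per volume, columns tx, ty, tz (mm),
#'   rx, ry, rz (radians).
#' @param head_radius sphere radius in mm used to convert rotations.
#' @return numeric vector of per-volume FD in mm.
#' @export
framewise_displacement <- function(mp, head_radius = 50) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6L)
    stop_arg("motion parameters must have 6 columns, got ", ncol(mp))
  if (nrow(mp) < 2L) stop_arg("need at least 2 volumes")
  d <- abs(diff(mp))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Exclude subjects whose scans exceed a framewise-displacement threshold
#'
#' A subject is removed entirely (both conditions) when the summary FD of
#' either scan exceeds `threshold`.
#'
#' @param motion named list of 6-column motion matrices; names must follow
#'   the cohort convention `s<ID>_<condition>`, or be paired with `subjects`.
#' @param threshold FD threshold in mm.
#' @param subjects integer subject id per motion entry (parsed from names if
#'   omitted).
#' @param summary `"mean"` (default) or `"max"` per-scan FD statistic.
#' @param head_radius sphere radius in mm for rotation conversion.
#' @return list with `retained_subjects`, `excluded_subjects`, and a
#'   data.frame `log` (scan, subject, summary FD, excluded flag).
#' @export
exclude_high_motion <- function(motion, threshold = 0.2, subjects = NULL,
                                summary = c("mean", "max"),
                                head_radius = 50) {
  summary <- match.arg(summary)
  stat <- if (summary == "mean") mean else max
  if (is.null(subjects)) {
    subjects <- as.integer(sub("^s0*([0-9]+)_.*$", "\\1", names(motion)))
    if (anyNA(subjects))
      stop_arg("cannot parse subject ids from motion names; pass `subjects`")
  }
  fd <- vapply(motion, function(m)
    stat(framewise_displacement(m, head_radius)), numeric(1))
  log <- data.frame(scan = names(motion) %||% seq_along(motion),
                    subject = subjects, fd = fd,
                    excluded = fd > threshold, row.names = NULL)
  excluded <- sort(unique(subjects[log$excluded]))
  list(retained_subjects = sort(setdiff(unique(subjects), excluded)),
       excluded_subjects = excluded, log = log)
}

#' Voxel-wise ALFF map
#'
#' Discrete Fourier transform of each in-mask voxel's (detrended) series with
#' no taper and no zero padding; the amplitude at bin k is 2|X_k|/N and ALFF
#' is the mean amplitude over bins whose frequency lies in the closed band.
#'
#' @param img a [bold_image()].
#' @param band length-2 frequency interval in Hz, within (0, Nyquist].
#' @param detrend remove the linear trend first (default TRUE; the ALFF
#'   definition assumes detrended input).
#' @param prefilter also zero out-of-band bins and return to the time domain
#'   before measuring, mimicking an explicit rectangular band-pass stage.
#'   Mathematically equivalent for the in-band average; off by default.
#' @return object of class `alff_map`: `values` (3D, 0 outside the mask),
#'   `mask`, `band`, `standardized` flag.
#' @export
compute_voxel_alff <- function(img, band = c(0.01, 0.08), detrend = TRUE,
                               prefilter = FALSE) {
  stopifnot(inherits(img, "bold_image"))
  band <- as.numeric(band)
  nyq <- 1 / (2 * img$tr)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop_arg("band must be an increasing positive interval")
  if (band[2] > nyq + 1e-12)
    stop_arg("band upper edge ", band[2], " Hz exceeds Nyquist ", nyq, " Hz")
  n <- dim(img$data)[4]
  bins <- .band_bins(n, img$tr, band)
  if (!length(bins))
    stop_arg("no DFT bin falls inside the band at N = ", n,
             ", TR = ", img$tr)
  flat <- matrix(img$data, ncol = n)
  ts <- t(flat[which(img$mask), , drop = FALSE])  # time x voxels
  if (detrend) ts <- linear_detrend(ts)
  sp <- stats::mvfft(ts)
  if (prefilter) {
    keep <- c(bins + 1L, n - bins + 1L)  # positive and mirrored bins
    filt <- matrix(0i, nrow(sp), ncol(sp))
    filt[keep, ] <- sp[keep, ]
    ts <- Re(stats::mvfft(filt, inverse = TRUE)) / n
    sp <- stats::mvfft(ts)
  }
  amp <- 2 * Mod(sp[bins + 1L, , drop = FALSE]) / n
  vals <- array(0, dim = dim(img$mask))
  vals[which(img$mask)] <- colMeans(amp)
  structure(list(values = vals, mask = img$mask, band = band,
                 standardized = FALSE), class = "alff_map")
}

#' Standardize an ALFF map by its whole-brain mean
#'
#' @param m an `alff_map`.
#' @return the map divided by its in-mask mean (which becomes exactly 1),
#'   with the `standardized` flag set. Idempotent.
#' @export
standardize_alff <- function(m) {
  stopifnot(inherits(m, "alff_map"))
  mu <- mean(m$values[m$mask])
  if (!is.finite(mu) || mu <= 0)
    stop_arg("cannot standardize: in-mask mean ALFF is ", mu)
  m$values[m$mask] <- m$values[m$mask] / mu
  m$standardized <- TRUE
  m
}

#' Average an ALFF map within each atlas region
#'
#' @param m a standardized `alff_map`.
#' @param atlas a [parcellation_atlas()] on the same voxel grid.
#' @return numeric vector of length R (named by region label); regions with
#'   no in-mask voxel are NA with a warning.
#' @export
region_average <- function(m, atlas) {
  stopifnot(inherits(m, "alff_map"), inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(m$values), dim(atlas$labels)))
    stop_arg("atlas and map dimensions differ")
  if (!isTRUE(m$standardized))
    warning("region_average called on a non-standardized ALFF map",
            call. = FALSE)
  use <- m$mask & atlas$labels > 0L
  lab <- atlas$labels[use]
  sums <- tabulate(lab, nbins = atlas$n_regions)
  out <- rep(NA_real_, atlas$n_regions)
  if (any(sums == 0L))
    warning("regions with no in-mask voxel: ",
            paste(which(sums == 0L), collapse = ", "), call. = FALSE)
  agg <- vapply(split(m$values[use], lab), mean, numeric(1))
  out[as.integer(names(agg))] <- agg
  names(out) <- seq_len(atlas$n_regions)
  out
}
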
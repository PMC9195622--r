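# Region-wise feature matrices for the paired classification problem.
# Rows are scans (2 per subject), columns are atlas regions; labels code the
# condition (+1 post-training, -1 pre-training) and subject ids carry the
# pairing.

#' Construct a paired feature matrix
#'
#' @param values numeric matrix, scans x regions.
#' @param subject_ids integer/character subject id per row.
#' @param condition `"pre"`/`"post"` per row.
#' @param region_labels integer label per column (defaults to 1..R).
#' @param drop_na drop columns containing missing values (regions absent
#'   from some mask) with a warning.
#' @return object of class `alff_features` with fields `values`, `labels`
#'   (+1 post / -1 pre), `subject_ids`, `condition`, `region_labels`.
#' @export
feature_matrix <- function(values, subject_ids, condition,
                           region_labels = NULL, drop_na = TRUE) {
  values <- as.matrix(values)
  if (length(subject_ids) != nrow(values) ||
      length(condition) != nrow(values))
    stop_arg("subject_ids and condition must have one entry per row")
  if (!all(condition %in% c("pre", "post")))
    stop_arg("condition entries must be 'pre' or 'post'")
  if (is.null(region_labels)) region_labels <- seq_len(ncol(values))
  region_labels <- as.integer(region_labels)
  if (length(region_labels) != ncol(values))
    stop_arg("region_labels must have one entry per column")
  tab <- table(subject_ids, condition)
  if (!all(tab == 1L))
    stop_arg("every subject needs exactly one 'pre' and one 'post' row")
  if (anyNA(values)) {
    bad <- which(colSums(is.na(values)) > 0L)
    if (!drop_na) stop_arg("missing values in regions ",
                           paste(region_labels[bad], collapse = ", "))
    warning("dropping regions with missing values: ",
            paste(region_labels[bad], collapse = ", "), call. = FALSE)
    values <- values[, -bad, drop = FALSE]
    region_labels <- region_labels[-bad]
  }
  colnames(values) <- paste0("region_", region_labels)
  structure(list(values = values,
                 labels = ifelse(condition == "post", 1, -1),
                 subject_ids = subject_ids,
                 condition = condition,
                 region_labels = region_labels),
            class = "alff_features")
}

#' Build the feature matrix from per-scan region ALFF vectors
#'
#' @param region_vectors matrix of region ALFF values, one row per scan.
#' @param subject_ids subject id per scan.
#' @param condition `"pre"`/`"post"` per scan.
#' @param ... passed to [feature_matrix()].
#' @return an `alff_features` object.
#' @export
build_feature_matrix <- function(region_vectors, subject_ids, condition, ...) {
  feature_matrix(region_vectors, subject_ids, condition, ...)
}

#' Subset the regions of a feature matrix
#'
#' @param fm an `alff_features` object.
#' @param regions region labels to keep.
#' @return the reduced `alff_features`.
#' @export
subset_regions <- function(fm, regions) {
  stopifnot(inherits(fm, "alff_features"))
  keep <- match(regions, fm$region_labels)
  if (anyNA(keep))
    stop_arg("regions not present: ",
             paste(regions[is.na(keep)], collapse = ", "))
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$region_labels <- fm$region_labels[keep]
  fm
}

#' Residualize features against a confound score
#'
#' Each feature column is replaced by the residuals of its least-squares
#' regression (with intercept) on the per-scan confound, removing e.g. the
#' face-expertise (CFMT) contribution before training-related selection.
#' Residual columns have mean zero and are exactly uncorrelated with the
#' confound.
#'
#' @param fm an `alff_features` object.
#' @param confound numeric vector, one value per scan row (each scan uses its
#'   own session's score).
#' @return the residualized `alff_features`.
#' @export
regress_out_confound <- function(fm, confound) {
  stopifnot(inherits(fm, "alff_features"))
  confound <- as.numeric(confound)
  if (length(confound) != nrow(fm$values))
    stop_arg("confound must have one value per scan row")
  if (stats::sd(confound) == 0) {
    warning("confound is constant; only the intercept (mean) is removed",
            call. = FALSE)
    fm$values <- scale(fm$values, center = TRUE, scale = FALSE)[, , drop = FALSE]
    return(fm)
  }
  qrx <- qr(cbind(1, confound))
  fm$values <- qr.resid(qrx, fm$values)
  fm
}

#' Rescale feature columns
#'
#' Default `"minmax"` maps each column onto [0, 1]; `"zscore"` standardizes
#' to zero mean and unit variance. Constant columns map to 0.5 (min-max) or
#' 0 (z-score) with a warning. When scaling must be learned on training rows
#' only, use the fold-aware option of the cross-validation routines instead.
#'
#' @param fm an `alff_features` object.
#' @param method `"minmax"` or `"zscore"`.
#' @return the rescaled `alff_features`.
#' @export
rescale_features <- function(fm, method = c("minmax", "zscore")) {
  stopifnot(inherits(fm, "alff_features"))
  method <- match.arg(method)
  v <- fm$values
  if (method == "minmax") {
    lo <- apply(v, 2, min)
    rng <- apply(v, 2, max) - lo
    const <- rng == 0
    if (any(const)) {
      warning("constant feature columns mapped to 0.5: ",
              paste(fm$region_labels[const], collapse = ", "), call. = FALSE)
      rng[const] <- 1
    }
    v <- sweep(sweep(v, 2, lo), 2, rng, "/")
    v[, const] <- 0.5
  } else {
    mu <- colMeans(v)
    s <- apply(v, 2, stats::sd)
    const <- s == 0
    if (any(const)) {
      warning("constant feature columns mapped to 0: ",
              paste(fm$region_labels[const], collapse = ", "), call. = FALSE)
      s[const] <- 1
    }
    v <- sweep(sweep(v, 2, mu), 2, s, "/")
  }
  fm$values <- v
  fm
}

#' Paired post-minus-pre differences per subject
#'
#' @param fm an `alff_features` object.
#' @return matrix of differences, one row per subject (sorted by id),
#'   columns as in `fm`.
#' @export
paired_differences <- function(fm) {
  stopifnot(inherits(fm, "alff_features"))
  subj <- sort(unique(fm$subject_ids))
  post <- fm$values[match(paste0(subj, "_post"),
                          paste0(fm$subject_ids, "_", fm$condition)), ,
                    drop = FALSE]
  pre <- fm$values[match(paste0(subj, "_pre"),
                         paste0(fm$subject_ids, "_", fm$condition)), ,
                   drop = FALSE]
  out <- post - pre
  rownames(out) <- subj
  out
}

#' Write / read a feature matrix as TSV
#'
#' Columns: `subject_id`, `condition`, then one `region_<label>` column per
#' region; one row per scan.
#'
#' @param fm an `alff_features` object.
#' @param path file path.
#' @return `path` invisibly / the reconstructed `alff_features`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "alff_features"))
  df <- data.frame(subject_id = fm$subject_ids, condition = fm$condition,
                   fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  rc <- grep("^region_", names(df))
  feature_matrix(as.matrix(df[, rc, drop = FALSE]),
                 subject_ids = df$subject_id, condition = df$condition,
                 region_labels = as.integer(sub("^region_", "", names(df)[rc])))
}

#' Write / read a 6-column motion-parameter file
#'
#' @param mp numeric matrix with 6 columns.
#' @param path file path.
#' @export
write_motion <- function(mp, path) {
  utils::write.table(format(mp, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  mp <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(mp) != 6L)
    stop_arg("motion file must have 6 columns, got ", ncol(mp))
  colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  mp
}
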
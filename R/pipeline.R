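# End-to-end orchestration: simulate -> QC -> ALFF -> select -> classify ->
# permute -> brain-behavior, with a reproducible JSON report.

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config()] describing the cohort to simulate
#'   (the packaged data source; file-based cohorts enter via
#'   [read_cohort_dir()]).
#' @param band ALFF frequency band, Hz.
#' @param fd_threshold framewise-displacement exclusion threshold, mm.
#' @param fd_summary per-scan FD summary statistic, `"mean"` or `"max"`.
#' @param alpha stage-1 screening threshold.
#' @param selection_mode `"paper_faithful"` (selection on the full sample,
#'   as in the emulated study) or `"nested"` (both selection stages re-run
#'   inside each outer cross-validation fold).
#' @param scheme cross-validation unit, `"subject"` or `"scan"`.
#' @param rescale_method `"minmax"` or `"zscore"`.
#' @param C soft-margin SVM cost.
#' @param B number of label permutations.
#' @param perm_scope `"selected"` (permute labels on the final feature set)
#'   or `"honest"` (re-run the full selection per permutation).
#' @param perm_pairing `"subject"` (coherent pair flips) or `"scan"`.
#' @param q FDR level for brain-behavior correlations.
#' @param corr_scope correlate behavior with the `"selected"` regions
#'   (default) or with `"all"` regions.
#' @param perm_seed seed for the permutation stream.
#' @param out_dir optional directory for per-stage artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       band = c(0.01, 0.08), fd_threshold = 0.2,
                       fd_summary = c("mean", "max"), alpha = 0.05,
                       selection_mode = c("paper_faithful", "nested"),
                       scheme = c("subject", "scan"),
                       rescale_method = c("minmax", "zscore"),
                       C = 1, B = 1000,
                       perm_scope = c("selected", "honest"),
                       perm_pairing = c("subject", "scan"),
                       q = 0.05, corr_scope = c("selected", "all"),
                       perm_seed = 7L, out_dir = NULL) {
  structure(list(
    synthetic = synthetic, band = as.numeric(band),
    fd_threshold = check_number(fd_threshold, "fd_threshold", lower = 0),
    fd_summary = match.arg(fd_summary), alpha = alpha,
    selection_mode = match.arg(selection_mode), scheme = match.arg(scheme),
    rescale_method = match.arg(rescale_method),
    C = check_number(C, "C", lower = 0, strict_lower = TRUE),
    B = check_count(B, "B"), perm_scope = match.arg(perm_scope),
    perm_pairing = match.arg(perm_pairing),
    q = check_number(q, "q", lower = 0, upper = 1, strict_lower = TRUE),
    corr_scope = match.arg(corr_scope),
    perm_seed = check_count(perm_seed, "perm_seed", min = 0L),
    out_dir = out_dir
  ), class = "run_config")
}

#' Region-wise ALFF features for a whole cohort
#'
#' Streams through the cohort scan by scan (regenerating images on demand if
#' the cohort was built with `images = FALSE`), computing detrended voxel
#' ALFF, whole-brain standardization, and region averages.
#'
#' @param cohort an `alff_cohort`.
#' @param band frequency band, Hz.
#' @param subjects subject ids to include (default all).
#' @return an `alff_features` matrix of standardized region ALFF.
#' @export
cohort_features <- function(cohort, band = c(0.01, 0.08), subjects = NULL) {
  stopifnot(inherits(cohort, "alff_cohort"))
  cfg <- cohort$config
  if (is.null(subjects)) subjects <- seq_len(cfg$n_subjects)
  rows <- list()
  ids <- character(0)
  conds <- character(0)
  for (s in subjects) {
    for (cond in c("pre", "post")) {
      nm <- sprintf("s%02d_%s", s, cond)
      img <- if (!is.null(cohort$images)) cohort$images[[nm]]
             else generate_subject_image(cfg, cohort$atlas, s, cond)
      m <- standardize_alff(compute_voxel_alff(img, band))
      rows[[nm]] <- region_average(m, cohort$atlas)
      ids <- c(ids, sprintf("s%02d", s))
      conds <- c(conds, cond)
    }
  }
  build_feature_matrix(do.call(rbind, rows), ids, conds)
}

# CFMT score per scan row: each scan is residualized against its own
# session's score
.cfmt_by_row <- function(fm, behavior) {
  subj_num <- as.integer(sub("^s0*", "", fm$subject_ids))
  i <- match(subj_num, behavior$subject)
  if (anyNA(i)) stop_arg("behavior table is missing subjects")
  ifelse(fm$condition == "post", behavior$cfmt_post[i], behavior$cfmt_pre[i])
}

# shared selection path: stage-1 screening, confound residualization,
# rescaling. Returns NULL if nothing survives screening.
.select_and_prepare <- function(fm, cfmt, alpha, scheme, rescale_method,
                                stage1_flip = NULL) {
  if (is.null(stage1_flip)) {
    s1 <- stage1_select(fm, alpha, scheme)
  } else {
    s1 <- .stage1_flipped(fm, alpha, stage1_flip)
  }
  if (!length(s1$regions)) return(NULL)
  fm2 <- subset_regions(fm, s1$regions)
  fm2 <- regress_out_confound(fm2, cfmt)
  fm2 <- suppressWarnings(rescale_features(fm2, rescale_method))
  list(stage1 = s1, fm = fm2)
}

# stage-1 screening under per-subject label flips (sign of the paired
# difference flips with the labels); used by the honest permutation
.stage1_flipped <- function(fm, alpha, flip) {
  d_all <- paired_differences(fm) * flip
  subj <- rownames(d_all)
  per_iter <- lapply(seq_along(subj), function(i) {
    p <- .paired_t_cols(d_all[-i, , drop = FALSE])$p
    fm$region_labels[which(p < alpha)]
  })
  list(regions = sort(unique(unlist(per_iter))), per_iteration = per_iter,
       alpha = alpha, scheme = "subject")
}

#' Honest permutation test: selection re-run per permutation
#'
#' For each permutation the subject pair labels are flipped coherently and
#' the entire selection path (stage-1 screening, confound residualization,
#' rescaling, RFE) is re-run before evaluating the LOOCV accuracy against
#' the permuted labels. This prices selection-induced optimism into the null
#' distribution, unlike the `"selected"` scope which permutes labels on the
#' features already chosen with the true labels.
#'
#' @param fm the full (unselected) `alff_features` matrix.
#' @param cfmt per-scan confound scores.
#' @param B number of permutations.
#' @param seed permutation stream seed.
#' @param alpha stage-1 threshold.
#' @param rescale_method column rescaling method.
#' @param C SVM cost.
#' @param batch batch-mode RFE.
#' @return a `permutation_result`.
#' @export
permutation_test_honest <- function(fm, cfmt, B = 200, seed = NULL,
                                    alpha = 0.05,
                                    rescale_method = "minmax", C = 1,
                                    batch = TRUE) {
  stopifnot(inherits(fm, "alff_features"))
  B <- check_count(B, "B")
  subj <- sort(unique(fm$subject_ids))
  subj_idx <- match(fm$subject_ids, subj)
  eval_once <- function(flip) {
    prep <- .select_and_prepare(fm, cfmt, alpha, "subject", rescale_method,
                                stage1_flip = flip)
    y <- fm$labels * flip[subj_idx]
    if (is.null(prep)) return(0.5)  # nothing selected: chance-level
    fm2 <- prep$fm
    fm2$labels <- y
    sel <- rfe_select(fm2, scheme = "subject", svm_cost = C, batch = batch)
    fold <- as.integer(factor(fm$subject_ids))
    .loocv_accuracy(fm2$values[, match(sel$stage2_regions,
                                       fm2$region_labels), drop = FALSE],
                    y, fold, C)
  }
  observed <- eval_once(rep(1, length(subj)))
  run <- function() vapply(seq_len(B), function(b)
    eval_once(sample(c(-1, 1), length(subj), replace = TRUE)), numeric(1))
  null_acc <- if (is.null(seed)) run() else .with_seed(seed, run())
  ge <- sum(null_acc >= observed - 1e-12)
  structure(list(observed_accuracy = observed, null_accuracies = null_acc,
                 p_raw = ge / B, p_add_one = (ge + 1) / (B + 1),
                 B = B, seed = seed, pairing = "subject"),
            class = "permutation_result")
}

#' Fully nested cross-validated evaluation
#'
#' Both selection stages (screening and RFE) are re-run inside each outer
#' leave-one-subject-out fold; residualization and rescaling parameters are
#' learned on the training rows and applied to the held-out scans. The
#' resulting metrics are free of selection leakage.
#'
#' @param fm the full `alff_features` matrix.
#' @param cfmt per-scan confound scores.
#' @param alpha stage-1 threshold.
#' @param rescale_method column rescaling method.
#' @param C SVM cost.
#' @param batch batch-mode RFE.
#' @return a `classification_metrics` object with an extra
#'   `selected_per_fold` list.
#' @export
nested_cv_evaluate <- function(fm, cfmt, alpha = 0.05,
                               rescale_method = "minmax", C = 1,
                               batch = TRUE) {
  stopifnot(inherits(fm, "alff_features"))
  subj <- sort(unique(fm$subject_ids))
  n <- nrow(fm$values)
  dec <- numeric(n)
  pred <- numeric(n)
  sel_per_fold <- vector("list", length(subj))
  names(sel_per_fold) <- subj
  for (u in seq_along(subj)) {
    te <- fm$subject_ids == subj[u]
    fm_tr <- feature_matrix(fm$values[!te, , drop = FALSE],
                            fm$subject_ids[!te], fm$condition[!te],
                            fm$region_labels)
    prep <- .select_and_prepare(fm_tr, cfmt[!te], alpha, "subject",
                                rescale_method)
    if (is.null(prep)) {  # nothing survives screening: constant classifier
      dec[te] <- 0
      pred[te] <- 1
      next
    }
    sel <- rfe_select(prep$fm, scheme = "subject", svm_cost = C,
                      batch = batch)
    sel_per_fold[[u]] <- sel$stage2_regions
    keep <- match(sel$stage2_regions, fm$region_labels)
    xtr_raw <- fm$values[!te, keep, drop = FALSE]
    xte_raw <- fm$values[te, keep, drop = FALSE]
    # residualize against the confound with train-fit coefficients
    qrx <- qr(cbind(1, cfmt[!te]))
    beta <- qr.coef(qrx, xtr_raw)
    xtr <- qr.resid(qrx, xtr_raw)
    xte <- xte_raw - cbind(1, cfmt[te]) %*% beta
    # rescale with train-learned parameters
    if (rescale_method == "minmax") {
      lo <- apply(xtr, 2, min)
      rng <- apply(xtr, 2, max) - lo
      rng[rng == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, lo), 2, rng, "/")
      xte <- sweep(sweep(xte, 2, lo), 2, rng, "/")
    } else {
      mu <- colMeans(xtr)
      s <- apply(xtr, 2, stats::sd)
      s[s == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, s, "/")
    }
    model <- train_linear_svm(xtr, fm$labels[!te], C)
    dec[te] <- predict(model, xte, type = "decision")
    pred[te] <- ifelse(dec[te] >= 0, 1, -1)
  }
  y <- fm$labels
  m <- compute_metrics(TP = sum(pred == 1 & y == 1),
                       FN = sum(pred == -1 & y == 1),
                       TN = sum(pred == -1 & y == -1),
                       FP = sum(pred == 1 & y == -1))
  roc <- roc_auc(dec, y)
  structure(c(m, list(auc = roc$auc, roc_points = roc$roc_points,
                      decision = dec, prediction = pred,
                      fold = as.integer(factor(fm$subject_ids)),
                      scheme = "subject", C = C,
                      selected_per_fold = sel_per_fold)),
            class = "classification_metrics")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> motion QC -> ALFF -> two-stage selection ->
#' LOOCV-SVM -> permutation test -> brain-behavior correlation and returns
#' a structured, deterministic report.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_report` list; see [validate_report()] for the schema.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- generate_cohort(cfg$synthetic, images = FALSE)

  qc <- exclude_high_motion(cohort$motion, cfg$fd_threshold,
                            summary = cfg$fd_summary)
  retained <- qc$retained_subjects
  if (!length(retained))
    stop_arg("pipeline: QC excluded every subject (threshold ",
             cfg$fd_threshold, " mm)")

  fm <- cohort_features(cohort, cfg$band, subjects = retained)
  behavior <- cohort$behavior
  cfmt <- .cfmt_by_row(fm, behavior)

  prep <- .select_and_prepare(fm, cfmt, cfg$alpha, cfg$scheme,
                              cfg$rescale_method)
  if (is.null(prep)) {
    # nothing survives screening (an expected outcome on null data): report
    # a chance-level constant classifier instead of aborting
    warning("no region survived stage-1 screening; reporting chance level",
            call. = FALSE)
    npos <- sum(fm$labels == 1)
    nneg <- sum(fm$labels == -1)
    sel <- structure(list(stage1_regions = integer(0),
                          stage2_regions = integer(0),
                          accuracy_trace = numeric(0),
                          removed_per_round = list(),
                          final_accuracy = NA_real_,
                          svm_cost = cfg$C, scheme = cfg$scheme),
                     class = "selection_result")
    prep <- list(stage1 = list(regions = integer(0)), fm = NULL)
    metrics <- c(compute_metrics(TP = npos, FN = 0, TN = 0, FP = nneg),
                 list(auc = 0.5))
    weights <- data.frame(region = integer(0), weight = numeric(0))
  } else {
    sel <- rfe_select(prep$fm, scheme = cfg$scheme, svm_cost = cfg$C)
    fm_final <- subset_regions(prep$fm, sel$stage2_regions)
    metrics <- if (cfg$selection_mode == "paper_faithful") {
      loocv_evaluate(fm_final$values, fm_final$labels, fm_final$subject_ids,
                     cfg$scheme, cfg$C)
    } else {
      nested_cv_evaluate(fm, cfmt, cfg$alpha, cfg$rescale_method, cfg$C)
    }
    # final hyperplane on all retained scans; +1 = post coding means positive
    # weights mark regions with higher ALFF after training
    final_model <- train_linear_svm(fm_final$values, fm_final$labels, cfg$C)
    weights <- data.frame(region = fm_final$region_labels,
                          weight = as.numeric(final_model$w))
  }

  perm <- if (is.null(prep$fm) || cfg$perm_scope == "honest" ||
              cfg$selection_mode == "nested") {
    permutation_test_honest(fm, cfmt, B = cfg$B, seed = cfg$perm_seed,
                            alpha = cfg$alpha,
                            rescale_method = cfg$rescale_method, C = cfg$C)
  } else {
    permutation_test(fm_final$values, fm_final$labels, fm_final$subject_ids,
                     B = cfg$B, seed = cfg$perm_seed, scheme = cfg$scheme,
                     pairing = cfg$perm_pairing, C = cfg$C,
                     observed = metrics$accuracy)
  }

  corr_regions <- if (cfg$corr_scope == "selected") sel$stage2_regions
                  else fm$region_labels
  deltas <- paired_differences(subset_regions(fm, corr_regions))
  subj_num <- as.integer(sub("^s0*", "", rownames(deltas)))
  bi <- match(subj_num, behavior$subject)
  bdelta <- data.frame(cfmt = behavior$cfmt_post[bi] - behavior$cfmt_pre[bi],
                       ret = behavior$ret_post[bi] - behavior$ret_pre[bi],
                       ret_rt = behavior$ret_rt_post[bi] -
                         behavior$ret_rt_pre[bi])
  corr <- if (length(corr_regions)) {
    colnames(deltas) <- corr_regions
    correlate_alff_behavior(deltas, bdelta, cfg$q)
  } else {
    data.frame(region = character(0), measure = character(0),
               r = numeric(0), p = numeric(0), p_adjusted = numeric(0),
               significant = logical(0))
  }

  report <- list(
    package = "alffsvm",
    version = as.character(utils::packageVersion("alffsvm")),
    config = .echo_config(cfg),
    qc = list(threshold_mm = cfg$fd_threshold, summary = cfg$fd_summary,
              excluded_subjects = qc$excluded_subjects,
              n_retained = length(retained),
              fd = qc$log),
    feature_counts = list(regions_total = cfg$synthetic$n_regions,
                          stage1 = length(prep$stage1$regions),
                          final = length(sel$stage2_regions)),
    selection = list(stage1_regions = prep$stage1$regions,
                     stage2_regions = sel$stage2_regions,
                     accuracy_trace = sel$accuracy_trace,
                     removed_per_round = sel$removed_per_round),
    weights = weights,
    metrics = list(TP = metrics$TP, FN = metrics$FN, TN = metrics$TN,
                   FP = metrics$FP, accuracy = metrics$accuracy,
                   sensitivity = metrics$sensitivity,
                   specificity = metrics$specificity, auc = metrics$auc),
    permutation = list(observed_accuracy = perm$observed_accuracy,
                       p_raw = perm$p_raw, p_add_one = perm$p_add_one,
                       B = perm$B, scope = cfg$perm_scope,
                       pairing = perm$pairing,
                       null_mean = mean(perm$null_accuracies)),
    behavior_tests = behavior_group_tests(behavior[bi, ]),
    correlations = as.data.frame(corr)
  )
  class(report) <- c("pipeline_report", "list")
  if (!is.null(cfg$out_dir))
    .write_artifacts(report, cfg$out_dir, fm, sel, metrics, perm)
  report
}

.echo_config <- function(cfg) {
  syn <- unclass(cfg$synthetic)
  out <- unclass(cfg)
  out$synthetic <- syn
  out$out_dir <- NULL
  out
}

.write_artifacts <- function(report, dir, fm, sel, metrics, perm) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report(report, file.path(dir, "report.json"))
  write_feature_matrix(fm, file.path(dir, "feature_matrix.tsv"))
  jsonlite::write_json(
    list(stage1_regions = sel$stage1_regions,
         stage2_regions = sel$stage2_regions,
         accuracy_trace = sel$accuracy_trace,
         removed_per_round = sel$removed_per_round,
         svm_cost = sel$svm_cost, scheme = sel$scheme),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(null_accuracy = perm$null_accuracies),
                   file.path(dir, "null_accuracies.csv"), row.names = FALSE)
  utils::write.csv(metrics$roc_points, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Validate a pipeline report against the bundled schema
#'
#' Checks the presence and basic type of every required key (a lightweight
#' structural validation driven by `inst/schema/report_schema.json`).
#'
#' @param report a `pipeline_report` or a list parsed from `report.json`.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "report_schema.json",
                             package = "alffsvm")
  schema <- jsonlite::read_json(schema_path)
  check_node <- function(node, spec, where) {
    for (key in names(spec)) {
      if (is.null(node[[key]]))
        stop_arg("report is missing '", where, key, "'")
      want <- spec[[key]]
      if (is.list(want)) {
        check_node(node[[key]], want, paste0(where, key, "."))
      } else {
        ok <- switch(want,
                     number = is.numeric(unlist(node[[key]])),
                     string = is.character(node[[key]]),
                     array = length(unlist(node[[key]])) >= 0,
                     table = is.list(node[[key]]) ||
                       is.data.frame(node[[key]]),
                     TRUE)
        if (!ok)
          stop_arg("report entry '", where, key, "' has the wrong type")
      }
    }
    invisible(TRUE)
  }
  check_node(report, schema, "")
  invisible(TRUE)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `atlas.nii`, `*_bold.nii`,
#'   `*_motion.txt`, and `behavior.csv`.
#' @return an `alff_cohort` (without a truth record unless `truth.json`
#'   is present).
#' @export
read_cohort_dir <- function(dir) {
  atlas <- parcellation_atlas(read_nifti(file.path(dir, "atlas.nii"))$data)
  bold_files <- sort(list.files(dir, "_bold\\.nii(\\.gz)?$",
                                full.names = TRUE))
  if (!length(bold_files)) stop_arg("no *_bold.nii files in ", dir)
  images <- list()
  motion <- list()
  for (f in bold_files) {
    nm <- sub("_bold\\.nii(\\.gz)?$", "", basename(f))
    nif <- read_nifti(f)
    images[[nm]] <- bold_image(nif$data, tr = nif$tr,
                               mask = atlas$labels > 0L)
    mf <- file.path(dir, paste0(nm, "_motion.txt"))
    if (file.exists(mf)) motion[[nm]] <- read_motion(mf)
  }
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"))
  truth_file <- file.path(dir, "truth.json")
  subj <- unique(as.integer(sub("^s0*([0-9]+)_.*$", "\\1", names(images))))
  tr <- images[[1]]$tr
  cfg <- synthetic_config(n_subjects = length(subj),
                          n_regions = atlas$n_regions,
                          volume_dims = dim(atlas$labels),
                          n_volumes = dim(images[[1]]$data)[4],
                          tr = if (tr > 0) tr else 2)
  structure(list(config = cfg, atlas = atlas, images = images,
                 motion = motion, behavior = behavior,
                 truth = if (file.exists(truth_file))
                   jsonlite::read_json(truth_file, simplifyVector = TRUE)
                 else NULL,
                 scan_names = names(images)),
            class = "alff_cohort")
}
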
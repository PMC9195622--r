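# Behavioral group comparisons and brain-behavior correlation with FDR
# control.

#' Mann-Whitney U test (two-sided)
#'
#' U counts the pairs in which a sample from `a` exceeds one from `b`
#' (ties contribute 1/2), i.e. U = R_a - n(n+1)/2 with midranks. Small
#' tie-free problems (n*m <= 200) use the exact null distribution; larger or
#' tied problems use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b non-empty numeric samples.
#' @param exact force (or forbid) the exact null; default decides by size
#'   and ties.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop_arg("both samples must be non-empty")
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- !has_ties && n * m <= 200
  if (exact && has_ties) {
    warning("ties present; falling back to the normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  if (exact) {
    p <- 2 * min(stats::pwilcox(U, n, m),
                 1 - stats::pwilcox(U - 1, n, m))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_tab <- table(c(a, b))
    nt <- n + m
    v <- n * m / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (v == 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
    p <- min(2 * stats::pnorm(-abs(z)), 1)
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p` (two-sided, from t = r sqrt((n-2)/(1-r^2))
#'   on n-2 df), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stop_arg("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("zero variance input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Sorts the p values, finds the largest k with p_(k) <= k q / m, and flags
#' the k smallest; also returns the monotone BH-adjusted p values.
#'
#' @param pvals p values in [0, 1] (NA allowed; never flagged, adjusted NA).
#' @param q target false discovery rate in (0, 1).
#' @return list with `significant` (logical), `p_adjusted`, `k` (number
#'   flagged).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  q <- check_number(q, "q", lower = 0, upper = 1, strict_lower = TRUE)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop_arg("p values must be in [0, 1]")
  p <- pvals[ok]
  m <- length(p)
  sig <- logical(length(pvals))
  adj <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    flag_sorted <- logical(m)
    if (length(k)) flag_sorted[seq_len(max(k))] <- TRUE
    adj_sorted <- pmin(rev(cummin(rev(ps * m / seq_len(m)))), 1)
    sig[ok][o] <- flag_sorted
    adj[ok][o] <- adj_sorted
  }
  list(significant = sig, p_adjusted = adj, k = sum(sig))
}

#' Correlate region-wise ALFF changes with behavioral changes
#'
#' Pearson correlation between per-subject post-minus-pre feature deltas and
#' each behavioral delta, with Benjamini-Hochberg correction across the full
#' region x measure family.
#'
#' @param feature_deltas numeric matrix, subjects x regions (post - pre),
#'   with region labels as column names.
#' @param behavior_deltas data.frame or matrix, subjects x measures
#'   (post - pre), aligned row-wise with `feature_deltas`.
#' @param q target false discovery rate.
#' @return data.frame of class `correlation_table`: `region`, `measure`,
#'   `r`, `p`, `p_adjusted`, `significant` -- the full table regardless of
#'   significance.
#' @export
correlate_alff_behavior <- function(feature_deltas, behavior_deltas,
                                    q = 0.05) {
  feature_deltas <- as.matrix(feature_deltas)
  behavior_deltas <- as.data.frame(behavior_deltas)
  if (nrow(feature_deltas) != nrow(behavior_deltas))
    stop_arg("feature and behavior deltas are misaligned")
  if (nrow(feature_deltas) < 3L)
    stop_arg("need at least 3 subjects")
  regions <- colnames(feature_deltas) %||% seq_len(ncol(feature_deltas))
  grid <- expand.grid(region = regions,
                      measure = names(behavior_deltas),
                      stringsAsFactors = FALSE)
  rp <- mapply(function(reg, meas) {
    x <- feature_deltas[, reg]
    y <- behavior_deltas[[meas]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    res <- pearson_r(x, y)
    c(res$r, res$p)
  }, grid$region, grid$measure)
  grid$r <- rp[1, ]
  grid$p <- rp[2, ]
  bh <- fdr_bh(grid$p, q)
  grid$p_adjusted <- bh$p_adjusted
  grid$significant <- bh$significant
  class(grid) <- c("correlation_table", "data.frame")
  grid
}

#' Pre/post behavioral group comparisons
#'
#' Mann-Whitney U comparisons of pre- versus post-training scores for each
#' behavioral measure (the convention of the study design this emulates,
#' despite the paired data); a paired Wilcoxon signed-rank alternative is
#' available behind `paired = TRUE`.
#'
#' @param behavior data.frame from [generate_behavior()] (columns
#'   `<measure>_pre` / `<measure>_post`).
#' @param measures measure stems to compare.
#' @param paired use the Wilcoxon signed-rank test instead.
#' @return data.frame with means, SDs and p values per measure.
#' @export
behavior_group_tests <- function(behavior,
                                 measures = c("ret", "ret_rt", "cfmt"),
                                 paired = FALSE) {
  rows <- lapply(measures, function(ms) {
    pre <- behavior[[paste0(ms, "_pre")]]
    post <- behavior[[paste0(ms, "_post")]]
    if (is.null(pre) || is.null(post))
      stop_arg("behavior table lacks columns for measure '", ms, "'")
    p <- if (paired)
      suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE)$p.value)
    else mann_whitney_u(pre, post)$p
    data.frame(measure = ms, mean_pre = mean(pre), sd_pre = stats::sd(pre),
               mean_post = mean(post), sd_post = stats::sd(post), p = p)
  })
  do.call(rbind, rows)
}
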
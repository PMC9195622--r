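# Independent oracles used to cross-check the implementation. Each one is a
# deliberately naive, literal re-implementation that shares no code with the
# package internals it checks.

# ALFF as literally "transform, square root of power, average over the band"
oracle_alff <- function(ts, tr, band = c(0.01, 0.08), detrend = TRUE) {
  n <- length(ts)
  if (detrend) ts <- stats::residuals(stats::lm(ts ~ seq_len(n)))
  sp <- stats::fft(ts)
  ks <- seq_len(floor(n / 2))
  freqs <- ks / (n * tr)
  amps <- vapply(ks, function(k) 2 * Mod(sp[k + 1]) / n, numeric(1))
  mean(amps[freqs >= band[1] & freqs <= band[2]])
}

# AUC by exhaustive pairwise comparison
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == -1]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up by direct loop
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  flags <- logical(m)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mwu_exact <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, u_of)
  mu <- length(a) * length(b) / 2
  # two-sided: as extreme or more, measured by distance from the mean
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# naive leave-one-unit-out accuracy via repeated explicit training
oracle_loocv_acc <- function(x, y, fold, C = 1) {
  x <- as.matrix(x)
  preds <- numeric(length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    model <- train_linear_svm(x[tr, , drop = FALSE], y[tr], C)
    preds[!tr] <- predict(model, x[!tr, , drop = FALSE])
  }
  mean(preds == y)
}

# brute-force simulator of the greedy batch elimination rule: per round,
# remove every feature whose single removal keeps the LOOCV accuracy,
# committing the batch only if its joint removal keeps the accuracy and
# otherwise removing the single best feature (ties: highest label out);
# an all-feature batch retains the best-removal feature (ties: lowest label)
oracle_rfe <- function(x, y, fold, labels = seq_len(ncol(x)), C = 1) {
  cur <- seq_len(ncol(x))
  tol <- 1e-12
  trace <- numeric(0)
  repeat {
    acc0 <- oracle_loocv_acc(x[, cur, drop = FALSE], y, fold, C)
    trace <- c(trace, acc0)
    if (length(cur) == 1L) break
    acc_i <- vapply(seq_along(cur), function(j)
      oracle_loocv_acc(x[, cur[-j], drop = FALSE], y, fold, C), numeric(1))
    rem <- which(acc_i >= acc0 - tol)
    if (!length(rem)) break
    done <- FALSE
    if (length(rem) > 1L) {
      after <- if (length(rem) == length(cur)) {
        best <- which(acc_i >= max(acc_i) - tol)
        cur[best[which.min(labels[cur[best]])]]
      } else cur[-rem]
      if (oracle_loocv_acc(x[, after, drop = FALSE], y, fold, C) >=
          acc0 - tol) {
        cur <- after
        done <- TRUE
      }
    }
    if (!done) {
      cand <- rem[acc_i[rem] >= max(acc_i[rem]) - tol]
      cur <- cur[-cand[which.max(labels[cur[cand]])]]
    }
  }
  list(final = labels[cur], trace = trace)
}

# small synthetic configurations reused across tests (kept tiny so the whole
# suite stays fast; region count is reduced from 246 where dimensionality is
# not the property under test)
tiny_cfg <- function(...) {
  synthetic_config(n_subjects = 10L, n_regions = 30L,
                   volume_dims = c(8L, 8L, 6L), n_volumes = 48L, ...)
}

small_cfg <- function(...) {
  synthetic_config(n_subjects = 16L, n_regions = 60L,
                   volume_dims = c(10L, 10L, 6L), n_volumes = 64L, ...)
}

# cohort -> features + per-row CFMT, the common test preamble
features_with_cfmt <- function(cfg) {
  cohort <- generate_cohort(cfg, images = FALSE)
  fm <- cohort_features(cohort)
  list(cohort = cohort, fm = fm,
       cfmt = alffsvm:::.cfmt_by_row(fm, cohort$behavior))
}
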
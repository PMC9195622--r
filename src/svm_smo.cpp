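#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Core SMO solver for the L1 soft-margin SVM dual on a dense training
// kernel:
//   min_a 0.5 a'Qa - e'a,  Q_ij = y_i y_j K_ij,  y'a = 0,  0 <= a <= C.
// Working-set selection is the maximal violating pair with stopping rule
// m(a) - M(a) < tol (KKT violation), as in LIBSVM.
static void smo_core(const std::vector<double>& K, int n, const double* y,
                     double C, double tol, int max_iter,
                     std::vector<double>& alpha, double& b, int& iters) {
  const double eps_bound = 1e-12;
  alpha.assign(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  int it = 0;
  double m = 0.0, M = 0.0;
  for (; it < max_iter; ++it) {
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    int ii = -1, jj = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0 && alpha[t] < C - eps_bound) ||
                       (y[t] < 0 && alpha[t] > eps_bound);
      const bool low = (y[t] > 0 && alpha[t] > eps_bound) ||
                       (y[t] < 0 && alpha[t] < C - eps_bound);
      if (up && v > m)  { m = v; ii = t; }
      if (low && v < M) { M = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || m - M < tol) break;
    double quad = K[(size_t)ii * n + ii] + K[(size_t)jj * n + jj] -
                  2.0 * K[(size_t)ii * n + jj];
    if (quad < 1e-12) quad = 1e-12;
    double step = (m - M) / quad;
    const double cap_i = (y[ii] > 0) ? (C - alpha[ii]) : alpha[ii];
    const double cap_j = (y[jj] > 0) ? alpha[jj] : (C - alpha[jj]);
    if (step > cap_i) step = cap_i;
    if (step > cap_j) step = cap_j;
    // feasible-direction update: a_i += y_i*step, a_j -= y_j*step
    alpha[ii] += y[ii] * step;
    alpha[jj] -= y[jj] * step;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * step * (K[(size_t)t * n + ii] - K[(size_t)t * n + jj]);
  }
  iters = it;
  // recompute violation bounds for the bias
  m = -std::numeric_limits<double>::infinity();
  M = std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    const bool up  = (y[t] > 0 && alpha[t] < C - eps_bound) ||
                     (y[t] < 0 && alpha[t] > eps_bound);
    const bool low = (y[t] > 0 && alpha[t] > eps_bound) ||
                     (y[t] < 0 && alpha[t] < C - eps_bound);
    if (up && v > m)  m = v;
    if (low && v < M) M = v;
  }
  if (!std::isfinite(m)) m = M;
  if (!std::isfinite(M)) M = m;
  b = 0.5 * (m + M);
}

// kernel matrix of X rows (column-major n x p)
static void gram(const double* X, int n, int p, std::vector<double>& K) {
  K.assign((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double dot = 0.0;
      for (int k = 0; k < p; ++k)
        dot += X[i + (size_t)k * n] * X[j + (size_t)k * n];
      K[(size_t)i * n + j] = dot;
      K[(size_t)j * n + i] = dot;
    }
}

// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C,
                 double tol = 1e-8, int max_iter = 200000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> K;
  gram(REAL(X), n, p, K);
  std::vector<double> alpha;
  double b = 0.0;
  int iters = 0;
  smo_core(K, n, REAL(y), C, tol, max_iter, alpha, b, iters);
  std::vector<double> w(p, 0.0);
  for (int k = 0; k < p; ++k) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += alpha[i] * y[i] * X(i, k);
    w[k] = acc;
  }
  double obj = 0.0, dual = 0.0;
  for (int k = 0; k < p; ++k) obj += 0.5 * w[k] * w[k];
  const double wnorm2 = 2.0 * obj;
  for (int i = 0; i < n; ++i) {
    double u = b;
    for (int k = 0; k < p; ++k) u += w[k] * X(i, k);
    const double h = 1.0 - y[i] * u;
    if (h > 0) obj += C * h;
    dual += alpha[i];
  }
  dual -= 0.5 * wnorm2;
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["obj_primal"] = obj,
                      _["obj_dual"] = dual,
                      _["iterations"] = iters);
}

static void unique_folds(const IntegerVector& fold, std::vector<int>& uniq) {
  uniq.clear();
  for (int i = 0; i < fold.size(); ++i) {
    bool seen = false;
    for (size_t u = 0; u < uniq.size(); ++u)
      if (uniq[u] == fold[i]) { seen = true; break; }
    if (!seen) uniq.push_back(fold[i]);
  }
}

// Leave-one-unit-out cross-validation on feature rows.
// fold: integer id per row; each unique id is held out once. y_train are
// the labels used for fitting (possibly permuted); decision values and sign
// predictions are returned for every row from the model that never saw its
// fold. scale_in_fold applies per-column min-max scaling learned on the
// training rows (constant training columns map to 0.5 everywhere).
// [[Rcpp::export(name = ".svm_loocv_cpp")]]
List svm_loocv_cpp(NumericMatrix X, NumericVector y_train, IntegerVector fold,
                   double C, bool scale_in_fold = false, double tol = 1e-6,
                   int max_iter = 200000) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector dec(n), pred(n);
  std::vector<int> uniq;
  unique_folds(fold, uniq);
  std::vector<double> Xtr, ytr, K, alpha, w(p);
  std::vector<int> tr_idx;
  for (size_t u = 0; u < uniq.size(); ++u) {
    const int f = uniq[u];
    tr_idx.clear(); ytr.clear();
    for (int i = 0; i < n; ++i)
      if (fold[i] != f) { tr_idx.push_back(i); ytr.push_back(y_train[i]); }
    const int ntr = (int)tr_idx.size();
    if (ntr == 0) stop("empty training fold");
    bool has_pos = false, has_neg = false;
    for (int i = 0; i < ntr; ++i) (ytr[i] > 0 ? has_pos : has_neg) = true;
    std::vector<double> lo(p, 0.0), rng(p, 1.0);
    if (scale_in_fold) {
      for (int k = 0; k < p; ++k) {
        double mn = R_PosInf, mx = R_NegInf;
        for (int i = 0; i < ntr; ++i) {
          const double v = X(tr_idx[i], k);
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
        lo[k] = mn; rng[k] = mx - mn;
      }
    }
    if (!has_pos || !has_neg) {
      // degenerate fold after permutation: constant classifier
      const double cls = has_pos ? 1.0 : -1.0;
      for (int i = 0; i < n; ++i)
        if (fold[i] == f) { dec[i] = cls; pred[i] = cls; }
      continue;
    }
    Xtr.assign((size_t)ntr * p, 0.0);
    for (int k = 0; k < p; ++k)
      for (int i = 0; i < ntr; ++i) {
        double v = X(tr_idx[i], k);
        if (scale_in_fold) v = (rng[k] > 0) ? (v - lo[k]) / rng[k] : 0.5;
        Xtr[i + (size_t)k * ntr] = v;
      }
    gram(Xtr.data(), ntr, p, K);
    double b = 0.0;
    int iters = 0;
    smo_core(K, ntr, ytr.data(), C, tol, max_iter, alpha, b, iters);
    for (int k = 0; k < p; ++k) {
      double acc = 0.0;
      for (int i = 0; i < ntr; ++i)
        acc += alpha[i] * ytr[i] * Xtr[i + (size_t)k * ntr];
      w[k] = acc;
    }
    for (int i = 0; i < n; ++i) {
      if (fold[i] != f) continue;
      double u2 = b;
      for (int k = 0; k < p; ++k) {
        double v = X(i, k);
        if (scale_in_fold) v = (rng[k] > 0) ? (v - lo[k]) / rng[k] : 0.5;
        u2 += w[k] * v;
      }
      dec[i] = u2;
      pred[i] = (u2 >= 0) ? 1.0 : -1.0;
    }
  }
  return List::create(_["decision"] = dec, _["prediction"] = pred);
}

// Same cross-validation driven by a precomputed full kernel matrix
// K = X X' (n x n). Decision values for held-out rows come from
// sum_i alpha_i y_i K(i, t) + b, so the features themselves are not needed;
// callers exploit this to share one kernel across permutations and to
// downdate it by rank-1 terms during feature elimination.
// [[Rcpp::export(name = ".svm_loocv_kernel_cpp")]]
List svm_loocv_kernel_cpp(NumericMatrix K, NumericVector y_train,
                          IntegerVector fold, double C, double tol = 1e-6,
                          int max_iter = 200000) {
  const int n = K.nrow();
  NumericVector dec(n), pred(n);
  std::vector<int> uniq;
  unique_folds(fold, uniq);
  std::vector<double> Ktr, ytr, alpha;
  std::vector<int> tr_idx;
  const double* Kp = REAL(K);
  for (size_t u = 0; u < uniq.size(); ++u) {
    const int f = uniq[u];
    tr_idx.clear(); ytr.clear();
    for (int i = 0; i < n; ++i)
      if (fold[i] != f) { tr_idx.push_back(i); ytr.push_back(y_train[i]); }
    const int ntr = (int)tr_idx.size();
    if (ntr == 0) stop("empty training fold");
    bool has_pos = false, has_neg = false;
    for (int i = 0; i < ntr; ++i) (ytr[i] > 0 ? has_pos : has_neg) = true;
    if (!has_pos || !has_neg) {
      const double cls = has_pos ? 1.0 : -1.0;
      for (int i = 0; i < n; ++i)
        if (fold[i] == f) { dec[i] = cls; pred[i] = cls; }
      continue;
    }
    Ktr.assign((size_t)ntr * ntr, 0.0);
    for (int i = 0; i < ntr; ++i)
      for (int j = 0; j < ntr; ++j)
        Ktr[(size_t)i * ntr + j] = Kp[tr_idx[i] + (size_t)n * tr_idx[j]];
    double b = 0.0;
    int iters = 0;
    smo_core(Ktr, ntr, ytr.data(), C, tol, max_iter, alpha, b, iters);
    for (int t = 0; t < n; ++t) {
      if (fold[t] != f) continue;
      double u2 = b;
      for (int i = 0; i < ntr; ++i)
        u2 += alpha[i] * ytr[i] * Kp[tr_idx[i] + (size_t)n * t];
      dec[t] = u2;
      pred[t] = (u2 >= 0) ? 1.0 : -1.0;
    }
  }
  return List::create(_["decision"] = dec, _["prediction"] = pred);
}
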
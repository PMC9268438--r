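#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Soft-margin C-SVM dual, solved by SMO with maximal-violating-pair working
// set selection on a precomputed kernel matrix.
//
//   max  sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
//   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
//
// Selection and the stopping rule use E_i = f_i - y_i with
// f_i = sum_j alpha_j y_j K_ij (no bias): the most violating pair is
// i = argmin E over I_up, j = argmax E over I_low, stop when
// E_j - E_i <= tol.

struct SmoResult {
  std::vector<double> alpha;
  double b;
  double objective;
  int iterations;
  bool converged;
};

static SmoResult smo_core(const double *K, int n, int ldk,
                          const std::vector<int> &idx,
                          const std::vector<double> &y,
                          double C, double tol, int max_iter) {
  // idx maps local problem rows to rows/cols of K (leading dimension ldk)
  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  int iter = 0;
  bool converged = false;
  const double bound_eps = 1e-12;

  while (iter < max_iter) {
    // working set selection
    int i = -1, j = -1;
    double Emin = R_PosInf, Emax = R_NegInf;
    for (int t = 0; t < n; ++t) {
      double E = f[t] - y[t];
      bool up  = (y[t] > 0 && alpha[t] < C - bound_eps) ||
                 (y[t] < 0 && alpha[t] > bound_eps);
      bool low = (y[t] > 0 && alpha[t] > bound_eps) ||
                 (y[t] < 0 && alpha[t] < C - bound_eps);
      if (up && E < Emin)  { Emin = E; i = t; }
      if (low && E > Emax) { Emax = E; j = t; }
    }
    if (i < 0 || j < 0 || Emax - Emin <= tol) { converged = true; break; }

    const double Kii = K[idx[i] + ldk * idx[i]];
    const double Kjj = K[idx[j] + ldk * idx[j]];
    const double Kij = K[idx[i] + ldk * idx[j]];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta < 1e-12) eta = 1e-12;

    double ai_old = alpha[i], aj_old = alpha[j];
    double aj_new = aj_old + y[j] * ((f[i] - y[i]) - (f[j] - y[j])) / eta;

    double L, H;
    if (y[i] * y[j] < 0) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai_old + y[i] * y[j] * (aj_old - aj_new);

    if (std::fabs(aj_new - aj_old) < 1e-15 && std::fabs(ai_new - ai_old) < 1e-15) {
      // numerically stuck on the violating pair: accept current iterate
      converged = (Emax - Emin) <= std::max(tol, 1e-9);
      break;
    }

    alpha[i] = ai_new;
    alpha[j] = aj_new;
    double di = (ai_new - ai_old) * y[i];
    double dj = (aj_new - aj_old) * y[j];
    for (int t = 0; t < n; ++t)
      f[t] += di * K[idx[t] + ldk * idx[i]] + dj * K[idx[t] + ldk * idx[j]];
    ++iter;
  }

  // bias: average of y - f over free support vectors, else KKT midpoint
  double bsum = 0.0; int nfree = 0;
  double up_max = R_NegInf, low_min = R_PosInf;
  for (int t = 0; t < n; ++t) {
    double v = y[t] - f[t];
    bool at0 = alpha[t] <= bound_eps, atC = alpha[t] >= C - bound_eps;
    if (!at0 && !atC) { bsum += v; ++nfree; }
    bool up  = (y[t] > 0 && !atC) || (y[t] < 0 && !at0);
    bool low = (y[t] > 0 && !at0) || (y[t] < 0 && !atC);
    if (up  && v > up_max)  up_max = v;
    if (low && v < low_min) low_min = v;
  }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else if (R_finite(up_max) && R_finite(low_min)) b = 0.5 * (up_max + low_min);
  else b = 0.0;

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (1.0 - 0.5 * y[t] * f[t]);

  SmoResult res;
  res.alpha = alpha; res.b = b; res.objective = obj;
  res.iterations = iter; res.converged = converged;
  return res;
}

// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C,
                   double tol, int max_iter) {
  int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("length(y) must match nrow(K)");
  std::vector<int> idx(n);
  std::vector<double> yy(n);
  for (int t = 0; t < n; ++t) { idx[t] = t; yy[t] = y[t]; }
  SmoResult r = smo_core(REAL(K), n, n, idx, yy, C, tol, max_iter);
  return List::create(_["alpha"] = NumericVector(r.alpha.begin(), r.alpha.end()),
                      _["b"] = r.b,
                      _["objective"] = r.objective,
                      _["iterations"] = r.iterations,
                      _["converged"] = r.converged);
}

// One-vs-one multiclass prediction with stratified-fold cross-validation,
// entirely on a precomputed kernel matrix. `cls` holds 0-based class codes,
// `fold` 1-based fold ids. Ties in the vote go to the larger summed decision
// value, then to the lower class code.
// [[Rcpp::export]]
List svm_cv_predict_cpp(NumericMatrix K, IntegerVector cls, IntegerVector fold,
                        double C, double tol, int max_iter) {
  int n = K.nrow();
  if (cls.size() != n || fold.size() != n) stop("cls/fold must match nrow(K)");
  int ncls = 0, nfold = 0;
  for (int t = 0; t < n; ++t) {
    if (cls[t] + 1 > ncls) ncls = cls[t] + 1;
    if (fold[t] > nfold) nfold = fold[t];
  }
  const double *Kp = REAL(K);
  IntegerVector pred(n, -1);

  for (int f = 1; f <= nfold; ++f) {
    std::vector<int> test, train;
    for (int t = 0; t < n; ++t) (fold[t] == f ? test : train).push_back(t);
    if (test.empty()) continue;
    int nt = (int)test.size();
    std::vector<int> votes(nt * ncls, 0);
    std::vector<double> score(nt * ncls, 0.0);

    for (int a = 0; a < ncls - 1; ++a) {
      for (int b = a + 1; b < ncls; ++b) {
        std::vector<int> idx; std::vector<double> y;
        for (size_t u = 0; u < train.size(); ++u) {
          int t = train[u];
          if (cls[t] == a) { idx.push_back(t); y.push_back(+1.0); }
          else if (cls[t] == b) { idx.push_back(t); y.push_back(-1.0); }
        }
        if (idx.empty()) continue;
        bool hasA = false, hasB = false;
        for (size_t u = 0; u < y.size(); ++u) (y[u] > 0 ? hasA : hasB) = true;
        if (!hasA || !hasB) continue;
        SmoResult r = smo_core(Kp, (int)idx.size(), n, idx, y, C, tol, max_iter);
        for (int u = 0; u < nt; ++u) {
          double dec = r.b;
          for (size_t v = 0; v < idx.size(); ++v)
            dec += r.alpha[v] * y[v] * Kp[test[u] + n * idx[v]];
          if (dec >= 0) votes[u * ncls + a] += 1; else votes[u * ncls + b] += 1;
          score[u * ncls + a] += dec;
          score[u * ncls + b] -= dec;
        }
      }
    }
    for (int u = 0; u < nt; ++u) {
      int best = 0;
      for (int c = 1; c < ncls; ++c) {
        int vb = votes[u * ncls + best], vc = votes[u * ncls + c];
        if (vc > vb || (vc == vb && score[u * ncls + c] > score[u * ncls + best]))
          best = c;
      }
      pred[test[u]] = best;
    }
  }

  int correct = 0, scored = 0;
  for (int t = 0; t < n; ++t) if (pred[t] >= 0) { ++scored; if (pred[t] == cls[t]) ++correct; }
  double acc = scored > 0 ? (double)correct / scored : NA_REAL;
  return List::create(_["accuracy"] = acc, _["pred"] = pred);
}
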
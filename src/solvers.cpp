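#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// SMO solver for the soft-margin linear SVM dual:
//   max_a  sum a_i - 1/2 sum_ij a_i a_j t_i t_j <x_i, x_j>
//   s.t.   0 <= a_i <= C,  sum a_i t_i = 0
// Working-set selection is the maximal violating pair; the update is the
// standard analytic two-variable subproblem with box clipping. Deterministic
// for fixed input. Problem sizes here are tiny (n <= a few hundred), so the
// n x n Gram matrix is built densely per fit.
// ---------------------------------------------------------------------------

struct SvmFit {
  std::vector<double> w;
  double b;
  std::vector<double> alpha;
  int iter;
  bool converged;
};

static SvmFit smo_solve(const double* X, const double* y, int n, int d,
                        double C, double tol, int maxit) {
  // X is n x d, column-major (R layout)
  std::vector<double> Q((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double dot = 0.0;
      for (int c = 0; c < d; ++c)
        dot += X[i + (size_t)c * n] * X[j + (size_t)c * n];
      double q = y[i] * y[j] * dot;
      Q[i + (size_t)j * n] = q;
      Q[j + (size_t)i * n] = q;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double TAU = 1e-12;
  int it = 0;
  bool converged = false;
  double m_up = 0.0, M_low = 0.0;

  for (it = 0; it < maxit; ++it) {
    int i = -1, j = -1;
    m_up = -HUGE_VAL;
    M_low = HUGE_VAL;
    for (int k = 0; k < n; ++k) {
      bool in_up  = (y[k] > 0 && alpha[k] < C) || (y[k] < 0 && alpha[k] > 0);
      bool in_low = (y[k] > 0 && alpha[k] > 0) || (y[k] < 0 && alpha[k] < C);
      double v = -y[k] * G[k];
      if (in_up && v > m_up)  { m_up = v;  i = k; }
      if (in_low && v < M_low) { M_low = v; j = k; }
    }
    if (i < 0 || j < 0 || m_up - M_low < tol) { converged = true; break; }

    double quad = Q[i + (size_t)i * n] + Q[j + (size_t)j * n]
                - 2.0 * y[i] * y[j] * Q[i + (size_t)j * n];
    if (quad <= 0) quad = TAU;
    double ai = alpha[i], aj = alpha[j];

    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = ai - aj;
      ai += delta; aj += delta;
      if (diff > 0) { if (aj < 0) { aj = 0; ai = diff; } }
      else          { if (ai < 0) { ai = 0; aj = -diff; } }
      if (diff > 0) { if (ai > C) { ai = C; aj = C - diff; } }
      else          { if (aj > C) { aj = C; ai = C + diff; } }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = ai + aj;
      ai -= delta; aj += delta;
      if (sum > C) { if (ai > C) { ai = C; aj = sum - C; } }
      else         { if (aj < 0) { aj = 0; ai = sum; } }
      if (sum > C) { if (aj > C) { aj = C; ai = sum - C; } }
      else         { if (ai < 0) { ai = 0; aj = sum; } }
    }

    double dai = ai - alpha[i], daj = aj - alpha[j];
    alpha[i] = ai; alpha[j] = aj;
    for (int k = 0; k < n; ++k)
      G[k] += Q[k + (size_t)i * n] * dai + Q[k + (size_t)j * n] * daj;
  }

  SvmFit fit;
  fit.alpha = alpha;
  fit.iter = it;
  fit.converged = converged;
  fit.w.assign(d, 0.0);
  for (int k = 0; k < n; ++k) {
    if (alpha[k] == 0.0) continue;
    double ay = alpha[k] * y[k];
    for (int c = 0; c < d; ++c)
      fit.w[c] += ay * X[k + (size_t)c * n];
  }
  // intercept: average -y_k G_k over free support vectors, else midpoint of
  // the KKT-feasible interval [m_up, M_low]
  double bsum = 0.0; int nfree = 0;
  for (int k = 0; k < n; ++k)
    if (alpha[k] > 0 && alpha[k] < C) { bsum += -y[k] * G[k]; ++nfree; }
  fit.b = nfree > 0 ? bsum / nfree : 0.5 * (m_up + M_low);
  return fit;
}

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(NumericMatrix X, NumericVector y, double C,
             double tol = 1e-6, int maxit = 200000) {
  int n = X.nrow(), d = X.ncol();
  SvmFit fit = smo_solve(REAL(X), REAL(y), n, d, C, tol, maxit);
  return List::create(_["w"] = NumericVector(fit.w.begin(), fit.w.end()),
                      _["b"] = fit.b,
                      _["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["iterations"] = fit.iter,
                      _["converged"] = fit.converged);
}

// Decode mask bits into column indices (0-based); masks handled as double so
// R can address all 2^30 - 1 of them.
static int mask_cols(double mask, int D, int* cols) {
  uint64_t m = (uint64_t)mask;
  int d = 0;
  for (int c = 0; c < D; ++c)
    if (m & (uint64_t(1) << c)) cols[d++] = c;
  return d;
}

// Cross-validation errors for a batch of channel-subset masks.
// X: N x D feature matrix, y: +-1 labels, fold: 1..K fold id per row.
// Returns the misclassification count per mask (ties y(x) == 0 predict -1).
// [[Rcpp::export(name = ".cv_errors_masks")]]
IntegerVector cv_errors_masks(NumericMatrix X, NumericVector y,
                              IntegerVector fold, int K,
                              NumericVector masks, double C,
                              double tol = 1e-6, int maxit = 200000) {
  int N = X.nrow(), D = X.ncol();
  int nm = masks.size();
  IntegerVector errors(nm);
  std::vector<int> cols(D);
  std::vector<double> Xtr((size_t)N * D), ytr(N);
  std::vector<int> test_rows(N);

  for (int mi = 0; mi < nm; ++mi) {
    int d = mask_cols(masks[mi], D, cols.data());
    int err = 0;
    for (int k = 1; k <= K; ++k) {
      int ntr = 0, nte = 0;
      for (int r = 0; r < N; ++r) {
        if (fold[r] == k) { test_rows[nte++] = r; }
        else { ytr[ntr++] = y[r]; }
      }
      // gather training submatrix (ntr x d, column-major)
      int ti = 0;
      for (int r = 0; r < N; ++r) {
        if (fold[r] == k) continue;
        for (int c = 0; c < d; ++c)
          Xtr[ti + (size_t)c * ntr] = X(r, cols[c]);
        ++ti;
      }
      SvmFit fit = smo_solve(Xtr.data(), ytr.data(), ntr, d, C, tol, maxit);
      for (int t = 0; t < nte; ++t) {
        int r = test_rows[t];
        double dec = fit.b;
        for (int c = 0; c < d; ++c) dec += fit.w[c] * X(r, cols[c]);
        int pred = dec > 0 ? 1 : -1;
        if (pred != (int)y[r]) ++err;
      }
    }
    errors[mi] = err;
    if (mi % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return errors;
}

// Full-data refit per mask; returns N_masks x D weight matrix (NA where the
// channel is absent from the subset) and the intercept vector.
// [[Rcpp::export(name = ".refit_masks")]]
List refit_masks(NumericMatrix X, NumericVector y, NumericVector masks,
                 double C, double tol = 1e-6, int maxit = 200000) {
  int N = X.nrow(), D = X.ncol();
  int nm = masks.size();
  NumericMatrix W(nm, D);
  std::fill(W.begin(), W.end(), NA_REAL);
  NumericVector b(nm);
  std::vector<int> cols(D);
  std::vector<double> Xs((size_t)N * D);

  for (int mi = 0; mi < nm; ++mi) {
    int d = mask_cols(masks[mi], D, cols.data());
    for (int c = 0; c < d; ++c)
      for (int r = 0; r < N; ++r)
        Xs[r + (size_t)c * N] = X(r, cols[c]);
    SvmFit fit = smo_solve(Xs.data(), REAL(y), N, d, C, tol, maxit);
    for (int c = 0; c < d; ++c) W(mi, cols[c]) = fit.w[c];
    b[mi] = fit.b;
  }
  return List::create(_["weights"] = W, _["intercept"] = b);
}

// ---------------------------------------------------------------------------
// Direct-form II transposed IIR filter, zero initial conditions. Used by the
// zero-phase (forward-backward) Butterworth band-pass in R.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    out[i] = yi;
  }
  return out;
}
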
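// Sequential minimal optimization for the C-SVC dual with an RBF kernel.
// Working-set selection follows the standard maximal-violating-pair rule
// with a second-order refinement for the second index.  The full kernel
// matrix is precomputed (problem sizes here are a few thousand instances
// at most), stored in single precision to halve memory.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>

using namespace Rcpp;

static inline double rbf_kernel(const double *xi, const double *xj, int k,
                                double gamma) {
  double s = 0.0;
  for (int t = 0; t < k; ++t) {
    double d = xi[t] - xj[t];
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
               double tol = 1e-3, double max_iter = 1e7) {
  const int n = X.nrow(), k = X.ncol();
  if (n < 2) stop("need at least two training instances");

  // row-major copy for cache locality in kernel evaluation
  std::vector<double> Xr((size_t)n * k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) Xr[(size_t)i * k + j] = X(i, j);

  std::vector<float> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0f;  // exp(0)
    for (int j = i + 1; j < n; ++j) {
      float v = (float)rbf_kernel(&Xr[(size_t)i * k], &Xr[(size_t)j * k], k,
                                  gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  // minimise 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0, with Q_ij = y_i y_j K_ij
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double TAU = 1e-12;
  double iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    // i: argmax over I_up of -y_t G_t
    int i = -1;
    double Gmax = -DBL_MAX, Gmax2 = -DBL_MAX;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v >= Gmax) { Gmax = v; i = t; }
      }
    }
    // j: second-order choice among I_low with violation against i
    int j = -1;
    double obj_min = DBL_MAX;
    const float *Ki = (i >= 0) ? &K[(size_t)i * n] : NULL;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C)) {
        double v = y[t] * G[t];  // = -(-y_t G_t)
        if (v > Gmax2) Gmax2 = v;
        double grad_diff = Gmax + v;
        if (i >= 0 && grad_diff > 0) {
          double quad = 2.0 - 2.0 * (double)Ki[t] * y[i] * y[t];
          if (quad <= 0) quad = TAU;
          double obj = -(grad_diff * grad_diff) / quad;
          if (obj <= obj_min) { obj_min = obj; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax + Gmax2 < tol) { converged = (i < 0 || j < 0 || Gmax + Gmax2 < tol); break; }

    const float *Kj = &K[(size_t)j * n];
    double Kii = Ki[i], Kjj = Kj[j], Kij = Ki[j];
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double di = (alpha[i] - ai_old) * y[i];
    double dj = (alpha[j] - aj_old) * y[j];
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * ((double)Ki[t] * di + (double)Kj[t] * dj);
    iter += 1;
  }

  // rho: decision is f(x) = sum_i alpha_i y_i K(x_i, x) - rho
  double rho;
  {
    double sum_free = 0.0;
    int n_free = 0;
    double ub = DBL_MAX, lb = -DBL_MAX;
    for (int t = 0; t < n; ++t) {
      double yG = y[t] * G[t];
      if (alpha[t] > 0 && alpha[t] < C) {
        sum_free += yG;
        ++n_free;
      } else if ((y[t] > 0 && alpha[t] >= C) || (y[t] < 0 && alpha[t] <= 0)) {
        if (yG > lb) lb = yG;
      } else {
        if (yG < ub) ub = yG;
      }
    }
    rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
  }

  std::vector<int> sv_idx;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12) sv_idx.push_back(t);
  int nsv = (int)sv_idx.size();
  NumericMatrix SV(nsv, k);
  NumericVector coef(nsv);
  IntegerVector idx(nsv);
  for (int s = 0; s < nsv; ++s) {
    int t = sv_idx[s];
    for (int j2 = 0; j2 < k; ++j2) SV(s, j2) = Xr[(size_t)t * k + j2];
    coef[s] = alpha[t] * y[t];
    idx[s] = t + 1;
  }

  return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                      _["sv_index"] = idx, _["iterations"] = iter,
                      _["converged"] = converged);
}

// [[Rcpp::export(name = ".svm_decision_values")]]
NumericVector svm_decision_values(NumericMatrix SV, NumericVector coef,
                                  double rho, double gamma, NumericMatrix X) {
  const int nsv = SV.nrow(), k = SV.ncol(), m = X.nrow();
  if (m > 0 && X.ncol() != k) stop("feature dimension mismatch");
  std::vector<double> S((size_t)nsv * k), Q((size_t)m * k);
  for (int i = 0; i < nsv; ++i)
    for (int j = 0; j < k; ++j) S[(size_t)i * k + j] = SV(i, j);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < k; ++j) Q[(size_t)i * k + j] = X(i, j);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double f = -rho;
    for (int s = 0; s < nsv; ++s)
      f += coef[s] *
           rbf_kernel(&S[(size_t)s * k], &Q[(size_t)i * k], k, gamma);
    out[i] = f;
  }
  return out;
}
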
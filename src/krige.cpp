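// Kriging linear-system solver.
//
// Per prediction point, solves the (possibly augmented) kriging system for
// the weights and returns the BLUP prediction and kriging variance.
// Methods: 0 = simple (known mean), 1 = ordinary (weights sum to 1 via a
// Lagrange multiplier), 2 = universal (first-order spatial trend 1, x, y).
// A global solve (one factorization, all prediction points) is used when
// kmax <= 0 or kmax >= n; otherwise each point uses its kmax nearest
// samples (moving neighborhood).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double corr_fun(double h, int family, double range) {
  switch (family) {
    case 0: return std::exp(-h / range);
    case 1: {
      if (h >= range) return 0.0;
      double u = h / range;
      return 1.0 - 1.5 * u + 0.5 * u * u * u;
    }
    default: {
      double u = h / range;
      return std::exp(-u * u);
    }
  }
}

static inline double cov_fun(double h, int family, double nugget,
                             double psill, double range) {
  if (h <= 1e-12) return nugget + psill;
  return psill * corr_fun(h, family, range);
}

static int n_trend(int method) {
  if (method == 0) return 0;      // simple
  if (method == 1) return 1;      // ordinary: constant
  return 3;                       // universal: 1, x, y
}

// Build the augmented system matrix for sample subset `idx`.
static mat build_A(const mat& coords, const uvec& idx, int family,
                   double nugget, double psill, double range, int method) {
  const int k = idx.n_elem;
  const int p = n_trend(method);
  mat A(k + p, k + p, fill::zeros);
  for (int i = 0; i < k; ++i) {
    A(i, i) = nugget + psill;
    for (int j = i + 1; j < k; ++j) {
      double h = std::sqrt(std::pow(coords(idx[i], 0) - coords(idx[j], 0), 2) +
                           std::pow(coords(idx[i], 1) - coords(idx[j], 1), 2));
      double c = cov_fun(h, family, nugget, psill, range);
      A(i, j) = c;
      A(j, i) = c;
    }
  }
  for (int i = 0; i < k; ++i) {
    if (p >= 1) { A(i, k) = 1.0; A(k, i) = 1.0; }
    if (p == 3) {
      A(i, k + 1) = coords(idx[i], 0); A(k + 1, i) = coords(idx[i], 0);
      A(i, k + 2) = coords(idx[i], 1); A(k + 2, i) = coords(idx[i], 1);
    }
  }
  return A;
}

// [[Rcpp::export(name = ".krige_cpp")]]
Rcpp::List krige_cpp(const arma::mat& coords, const arma::vec& z,
                     int family, double nugget, double psill, double range,
                     const arma::mat& pred, int method, double sk_mean,
                     int kmax, bool want_weights) {
  const int n = coords.n_rows;
  const int m = pred.n_rows;
  const int p = n_trend(method);
  const double C0 = nugget + psill;
  vec out_pred(m, fill::zeros), out_var(m, fill::zeros);
  mat W;
  if (want_weights) W.zeros(m, n);

  const bool global = (kmax <= 0 || kmax >= n);

  if (global) {
    uvec all = regspace<uvec>(0, n - 1);
    mat A = build_A(coords, all, family, nugget, psill, range, method);
    mat Ainv;
    if (!inv(Ainv, A)) Ainv = pinv(A);
    vec b(n + p);
    for (int q = 0; q < m; ++q) {
      for (int i = 0; i < n; ++i) {
        double h = std::sqrt(std::pow(pred(q, 0) - coords(i, 0), 2) +
                             std::pow(pred(q, 1) - coords(i, 1), 2));
        b[i] = cov_fun(h, family, nugget, psill, range);
      }
      if (p >= 1) b[n] = 1.0;
      if (p == 3) { b[n + 1] = pred(q, 0); b[n + 2] = pred(q, 1); }
      vec x = Ainv * b;
      double w_z = dot(x.head(n), z);
      if (method == 0) {
        out_pred[q] = sk_mean + w_z - dot(x.head(n), vec(n, fill::ones)) * sk_mean;
        out_var[q] = C0 - dot(x.head(n), b.head(n));
      } else {
        out_pred[q] = w_z;
        out_var[q] = C0 - dot(x, b);
      }
      if (want_weights) W.row(q) = x.head(n).t();
    }
  } else {
    std::vector<std::pair<double, int>> dk(n);
    for (int q = 0; q < m; ++q) {
      for (int i = 0; i < n; ++i) {
        double d2 = std::pow(pred(q, 0) - coords(i, 0), 2) +
                    std::pow(pred(q, 1) - coords(i, 1), 2);
        dk[i] = std::make_pair(d2, i);
      }
      std::nth_element(dk.begin(), dk.begin() + kmax - 1, dk.end());
      uvec idx(kmax);
      for (int i = 0; i < kmax; ++i) idx[i] = dk[i].second;
      idx = sort(idx);  // stable local ordering -> deterministic systems
      mat A = build_A(coords, idx, family, nugget, psill, range, method);
      vec b(kmax + p);
      for (int i = 0; i < kmax; ++i) {
        double h = std::sqrt(std::pow(pred(q, 0) - coords(idx[i], 0), 2) +
                             std::pow(pred(q, 1) - coords(idx[i], 1), 2));
        b[i] = cov_fun(h, family, nugget, psill, range);
      }
      if (p >= 1) b[kmax] = 1.0;
      if (p == 3) { b[kmax + 1] = pred(q, 0); b[kmax + 2] = pred(q, 1); }
      vec x;
      if (!solve(x, A, b, solve_opts::fast)) x = pinv(A) * b;
      vec zi(kmax);
      for (int i = 0; i < kmax; ++i) zi[i] = z[idx[i]];
      double w_z = dot(x.head(kmax), zi);
      if (method == 0) {
        double wsum = dot(x.head(kmax), vec(kmax, fill::ones));
        out_pred[q] = sk_mean + w_z - wsum * sk_mean;
        out_var[q] = C0 - dot(x.head(kmax), b.head(kmax));
      } else {
        out_pred[q] = w_z;
        out_var[q] = C0 - dot(x, b);
      }
      if (want_weights)
        for (int i = 0; i < kmax; ++i) W(q, idx[i]) = x[i];
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("pred") = out_pred,
      Rcpp::Named("var") = out_var);
  if (want_weights) out["weights"] = W;
  return out;
}
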
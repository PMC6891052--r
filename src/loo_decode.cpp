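// Leave-one-out shrinkage-Mahalanobis decoding kernel.
//
// For every test trial and every window offset, the covariance is the
// Ledoit-Wolf shrinkage estimate computed from all trials except the test
// trial, class means are computed from the same training trials, and the
// Mahalanobis distance of the test trial to each class mean is taken. The
// returned distance per (trial, class) is the minimum across offsets.
//
// The per-trial training covariance is obtained from the full-data raw
// scatter by a rank-one downdate, so one offset costs O(n^2 p + n p^3)
// rather than O(n^2 p^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Ledoit-Wolf shrinkage covariance of rows of X (used for cross-checking and
// as the reference implementation of the intensity formula).
static mat lw_shrink_cov(const mat& X) {
  const uword n = X.n_rows, p = X.n_cols;
  rowvec mu = mean(X, 0);
  mat Xc = X.each_row() - mu;
  mat S = (Xc.t() * Xc) / double(n);
  double m = trace(S) / double(p);
  mat target = m * eye<mat>(p, p);
  double d2 = accu(square(S - target));
  if (d2 <= 0.0) return target;
  // sum_k ||x_k x_k' - S||^2 = sum_k (x_k'x_k)^2 - n ||S||^2
  vec sq = sum(square(Xc), 1);
  double sum4 = accu(square(sq));
  double b2bar = (sum4 - double(n) * accu(square(S))) / double(n * n);
  double b2 = std::min(std::max(b2bar, 0.0), d2);
  double rho = b2 / d2;
  return rho * target + (1.0 - rho) * S;
}

// [[Rcpp::export]]
arma::mat cpp_lw_cov(const arma::mat& X) { return lw_shrink_cov(X); }

// X: n x p x K cube (trials x features x window offsets)
// labels: 1..C class of each trial
// Returns n x C matrix of min-over-offset LOO distances (NaN where a class
// has no training trials).
// [[Rcpp::export]]
arma::mat cpp_loo_min_dist(const arma::cube& X, const arma::ivec& labels,
                           const int n_class) {
  const uword n = X.n_rows, p = X.n_cols, K = X.n_slices;
  const uword C = (uword)n_class;
  mat D(n, C);
  D.fill(datum::inf);
  uvec counts(C, fill::zeros);
  for (uword i = 0; i < n; ++i) counts(labels(i) - 1) += 1;
  const mat I = eye<mat>(p, p);

  for (uword k = 0; k < K; ++k) {
    const mat Xk = X.slice(k);
    const rowvec csum_all = sum(Xk, 0);
    const mat Rscat = Xk.t() * Xk; // raw scatter
    const vec sq = sum(square(Xk), 1); // ||x_i||^2
    mat csum(C, p, fill::zeros);
    for (uword i = 0; i < n; ++i) csum.row(labels(i) - 1) += Xk.row(i);

    for (uword i = 0; i < n; ++i) {
      const double m = double(n - 1);
      const rowvec xi = Xk.row(i);
      const rowvec mu = (csum_all - xi) / m;
      // ML covariance of the training rows via downdate
      mat S = (Rscat - xi.t() * xi) / m - mu.t() * mu;
      const double m2 = trace(S) / double(p);
      const double d2 = accu(square(S - m2 * I));
      double rho = 1.0;
      if (d2 > 0.0) {
        // sum over training rows of (||x_k - mu||^2)^2
        const vec xm = Xk * mu.t(); // x_k . mu
        const double mu2 = dot(mu, mu);
        vec dev = sq - 2.0 * xm + mu2;
        dev(i) = 0.0; // exclude the test row
        const double sum4 = accu(square(dev));
        const double b2bar = (sum4 - m * accu(square(S))) / (m * m);
        rho = std::min(std::max(b2bar, 0.0), d2) / d2;
      }
      const mat Sigma = rho * m2 * I + (1.0 - rho) * S;
      mat L;
      if (!chol(L, Sigma, "lower")) {
        Rcpp::stop("shrinkage covariance not positive definite");
      }
      for (uword c = 0; c < C; ++c) {
        const uword cnt = counts(c) - (labels(i) == (sword)c + 1 ? 1 : 0);
        if (cnt == 0) { D(i, c) = datum::nan; continue; }
        const rowvec mu_c =
            (csum.row(c) -
             (labels(i) == (sword)c + 1 ? xi : rowvec(p, fill::zeros))) /
            double(cnt);
        const vec delta = (xi - mu_c).t();
        const vec z = solve(trimatl(L), delta);
        const double dist = std::sqrt(dot(z, z));
        if (dist < D(i, c)) D(i, c) = dist;
      }
    }
  }
  D.replace(datum::inf, datum::nan);
  return D;
}
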
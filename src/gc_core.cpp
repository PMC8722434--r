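#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// All-pairs bivariate Granger causality for one epoch.
//
// X is channels x samples. For every ordered pair (target i, source j) the
// full model regresses x_i(n) on p lags of x_i and x_j (no intercept; the
// series are band-passed and effectively zero-mean), the restricted model on
// p lags of x_i alone, both by OLS over the common window n = p+1..N.
// Residual variances use the 1/M normalizer over the M = N - p fitted
// samples. Entry (i, j) of the result is GC_{j -> i} = ln(Vr_i / Vf_ij).
//
// The lag design is shared across pairs: with G = L'L and c = L'y
// precomputed once, each pair costs one symmetric 2p x 2p solve with two
// right-hand sides (both directions of the pair).
//
// [[Rcpp::export]]
arma::mat gc_matrix_cpp(const arma::mat& X, const int p, const double eps,
                        const bool clip) {
  const int C = X.n_rows;
  const int N = X.n_cols;
  if (p < 1) Rcpp::stop("order p must be >= 1");
  if (N < 5 * p)
    Rcpp::stop("epoch too short: %d samples for order-%d fits (need >= 5p)", N, p);
  const int M = N - p;

  mat L(M, C * p);
  mat Y(M, C);
  for (int c = 0; c < C; ++c) {
    for (int k = 1; k <= p; ++k)
      L.col(c * p + (k - 1)) = X.row(c).subvec(p - k, N - k - 1).t();
    Y.col(c) = X.row(c).subvec(p, N - 1).t();
  }
  const mat G = L.t() * L;
  const mat Cxy = L.t() * Y;
  const rowvec yy = sum(square(Y), 0);

  // restricted (own-past-only) residual variances
  vec Vr(C);
  for (int i = 0; i < C; ++i) {
    const uvec idx = regspace<uvec>(i * p, i * p + p - 1);
    const vec rhs = Cxy(idx, uvec({(uword)i}));
    vec b;
    if (!solve(b, G(idx, idx), rhs, solve_opts::likely_sympd + solve_opts::no_approx))
      Rcpp::stop("singular restricted fit for channel %d", i + 1);
    Vr(i) = (yy(i) - dot(b, rhs)) / M;
  }

  mat gc(C, C, fill::zeros);
  uvec idx(2 * p);
  for (int i = 0; i < C; ++i) {
    for (int j = i + 1; j < C; ++j) {
      for (int k = 0; k < p; ++k) {
        idx(k) = i * p + k;
        idx(p + k) = j * p + k;
      }
      const mat rhs = Cxy(idx, uvec({(uword)i, (uword)j}));
      mat B;
      if (!solve(B, G(idx, idx), rhs, solve_opts::likely_sympd + solve_opts::no_approx))
        Rcpp::stop("singular bivariate fit for channel pair (%d, %d)", i + 1, j + 1);
      const double Vf_i = (yy(i) - dot(B.col(0), rhs.col(0))) / M;
      const double Vf_j = (yy(j) - dot(B.col(1), rhs.col(1))) / M;
      double g_ji = std::log(std::max(Vr(i), eps) / std::max(Vf_i, eps)); // j -> i
      double g_ij = std::log(std::max(Vr(j), eps) / std::max(Vf_j, eps)); // i -> j
      if (clip) {
        g_ji = std::max(g_ji, 0.0);
        g_ij = std::max(g_ij, 0.0);
      }
      gc(i, j) = g_ji;
      gc(j, i) = g_ij;
    }
  }
  return gc;
}
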
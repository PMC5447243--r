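// Weighted-least-squares sweep over a grid of candidate environmental-
// response features. For each grid row the raw feature is scaled to
// mean 0 / range 1, the age x response interaction is formed, and the
// weighted residual mean square of the full design fit is recorded.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// F: G x N raw (unscaled) response features, one grid point per row.
// X0: N x m fixed design columns (intercept first, degenerate cols removed).
// d: scaled age vector (length N); y: response; w: positive weights.
// Returns the weighted MSE (sum w e^2 / N) for each grid row.
// [[Rcpp::export(name = ".grid_wls_mse")]]
Rcpp::NumericVector grid_wls_mse(const arma::mat& F, const arma::mat& X0,
                                 const arma::vec& d, const arma::vec& y,
                                 const arma::vec& w) {
  const uword G = F.n_rows, N = F.n_cols, m = X0.n_cols;
  if (d.n_elem != N || y.n_elem != N || w.n_elem != N)
    Rcpp::stop("dimension mismatch");

  const mat X0W = X0.each_col() % w;          // N x m
  const mat A00 = X0.t() * X0W;               // m x m
  const vec b0 = X0W.t() * y;                 // m
  const double yWy = dot(w % y, y);

  // fixed-columns-only fit (used for degenerate feature rows)
  vec c0;
  bool ok0 = solve(c0, A00, b0, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok0) c0 = pinv(A00) * b0;
  double rss0 = yWy - dot(b0, c0);
  if (rss0 < 0) rss0 = 0;

  Rcpp::NumericVector out(G);
  vec r(N), dr(N);
  mat A(m + 2, m + 2);
  vec b(m + 2), coef;

  for (uword g = 0; g < G; ++g) {
    const rowvec raw = F.row(g);
    const double rng = raw.max() - raw.min();
    if (rng < 1e-12) { out[g] = rss0 / N; continue; }
    r = raw.t() / rng;
    r -= mean(r);
    dr = d % r;

    const vec wr = w % r, wdr = w % dr;
    A.submat(0, 0, m - 1, m - 1) = A00;
    const vec a0r = X0.t() * wr, a0dr = X0.t() * wdr;
    A.submat(0, m, m - 1, m) = a0r;
    A.submat(0, m + 1, m - 1, m + 1) = a0dr;
    A.submat(m, 0, m, m - 1) = a0r.t();
    A.submat(m + 1, 0, m + 1, m - 1) = a0dr.t();
    A(m, m) = dot(wr, r);
    A(m, m + 1) = dot(wr, dr);
    A(m + 1, m) = A(m, m + 1);
    A(m + 1, m + 1) = dot(wdr, dr);
    b.subvec(0, m - 1) = b0;
    b(m) = dot(wr, y);
    b(m + 1) = dot(wdr, y);

    bool ok = solve(coef, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) coef = pinv(A) * b;
    double rss = yWy - dot(b, coef);
    if (rss < 0) rss = 0;
    out[g] = rss / N;
  }
  return out;
}
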
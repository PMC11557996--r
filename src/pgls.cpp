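// Core GLS machinery under a lambda-scaled phylogenetic covariance.
//
// V(lambda) = lambda * C + (1 - lambda) * diag(C), i.e. off-diagonal
// covariances shrink toward zero while root-to-tip variances are kept.
// Writing D = diag(C) and K = D^{-1/2} C D^{-1/2},
//   V(lambda) = D^{1/2} (lambda K + (1 - lambda) I) D^{1/2},
// so a single symmetric eigendecomposition of K turns every lambda
// evaluation into a weighted least-squares problem: O(n k^2) per lambda
// after one O(n^3) factorisation. This is what makes profiling lambda over
// a fine grid (and bootstrapping the whole fit) affordable.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Profile log-likelihood at a fixed lambda, maximised over beta and sigma2.
// On success fills beta, XtWX (= X' V^-1 X) and s2 (ML residual rate).
static double prof_loglik(const double lam, const vec &eval, const vec &yt,
                          const mat &Xt, const double logdetD, vec &beta,
                          mat &XtWX, double &s2) {
  const uword n = yt.n_elem;
  vec d = lam * eval + (1.0 - lam);
  if (d.min() <= 1e-12) return -datum::inf;
  vec w = 1.0 / d;
  mat XtW = Xt.each_col() % w;
  XtWX = Xt.t() * XtW;
  vec XtWy = XtW.t() * yt;
  vec b;
  bool ok = solve(b, XtWX, XtWy, solve_opts::no_approx);
  if (!ok) return -datum::inf;
  vec r = yt - Xt * b;
  double rss = dot(w, r % r);
  if (!std::isfinite(rss) || rss < 0) return -datum::inf;
  s2 = rss / n;
  if (s2 < 1e-290) return datum::inf;  // zero-residual degeneracy
  beta = b;
  return -0.5 * n * (std::log(2.0 * datum::pi) + std::log(s2) + 1.0) -
         0.5 * (accu(log(d)) + logdetD);
}

// Maximum-likelihood GLS with Pagel's lambda profiled over a grid in [0, 1],
// optionally refined by golden-section search between the grid neighbours of
// the winner. Ties on the grid are broken toward the smaller lambda.
// [[Rcpp::export]]
Rcpp::List cpp_pgls_ml(const arma::vec &y, const arma::mat &X,
                       const arma::mat &C, const arma::vec &grid,
                       const bool refine, const double tol) {
  const uword n = y.n_elem, k = X.n_cols;
  if (C.n_rows != n || C.n_cols != n)
    Rcpp::stop("covariance dimension does not match response length");
  if (X.n_rows != n) Rcpp::stop("design rows do not match response length");
  vec D = C.diag();
  if (D.min() <= 0) Rcpp::stop("non-positive diagonal in phylogenetic covariance");
  vec s = sqrt(D);
  mat K = C;
  K.each_col() /= s;
  K.each_row() /= s.t();
  vec eval;
  mat Q;
  if (!eig_sym(eval, Q, K)) Rcpp::stop("eigendecomposition failed");
  // clamp tiny negative eigenvalues from roundoff (K is PSD by construction)
  eval.transform([](double v) { return v < 0 ? 0.0 : v; });
  const double logdetD = accu(log(D));
  vec yt = Q.t() * (y / s);
  mat Xt = Q.t() * (X.each_col() / s);

  vec grid_ll(grid.n_elem);
  double best_ll = -datum::inf, best_lam = grid.min();
  vec beta_tmp;
  mat XtWX_tmp;
  double s2_tmp = NA_REAL;
  uword best_i = 0;
  for (uword i = 0; i < grid.n_elem; ++i) {
    double ll = prof_loglik(grid(i), eval, yt, Xt, logdetD, beta_tmp, XtWX_tmp, s2_tmp);
    grid_ll(i) = ll;
    if (ll > best_ll) {  // strict: ties keep the earlier (smaller) lambda
      best_ll = ll;
      best_lam = grid(i);
      best_i = i;
    }
  }
  if (!std::isfinite(best_ll) && best_ll < 0)
    Rcpp::stop("likelihood not finite at any candidate lambda (singular fit?)");

  if (refine && grid.n_elem > 1 && std::isfinite(best_ll)) {
    double lo = best_i > 0 ? grid(best_i - 1) : grid(0);
    double hi = best_i + 1 < grid.n_elem ? grid(best_i + 1) : grid(grid.n_elem - 1);
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double a = lo, b = hi;
    double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
    double f1 = prof_loglik(c1, eval, yt, Xt, logdetD, beta_tmp, XtWX_tmp, s2_tmp);
    double f2 = prof_loglik(c2, eval, yt, Xt, logdetD, beta_tmp, XtWX_tmp, s2_tmp);
    int iter = 0;
    while (b - a > tol && iter++ < 200) {
      if (f1 < f2) {
        a = c1; c1 = c2; f1 = f2;
        c2 = a + gr * (b - a);
        f2 = prof_loglik(c2, eval, yt, Xt, logdetD, beta_tmp, XtWX_tmp, s2_tmp);
      } else {
        b = c2; c2 = c1; f2 = f1;
        c1 = b - gr * (b - a);
        f1 = prof_loglik(c1, eval, yt, Xt, logdetD, beta_tmp, XtWX_tmp, s2_tmp);
      }
    }
    double lam_ref = (a + b) / 2.0;
    double ll_ref = prof_loglik(lam_ref, eval, yt, Xt, logdetD, beta_tmp, XtWX_tmp, s2_tmp);
    if (ll_ref > best_ll + 1e-9 ||
        (std::abs(ll_ref - best_ll) <= 1e-9 && lam_ref < best_lam)) {
      best_ll = ll_ref;
      best_lam = lam_ref;
    }
  }

  vec beta;
  mat XtWX;
  double s2 = NA_REAL;
  double ll = prof_loglik(best_lam, eval, yt, Xt, logdetD, beta, XtWX, s2);
  bool degenerate = !std::isfinite(ll) && ll > 0;
  mat cov_unscaled;
  if (!degenerate) {
    if (!inv_sympd(cov_unscaled, XtWX)) {
      if (!inv(cov_unscaled, XtWX)) Rcpp::stop("singular design matrix");
    }
  } else {
    cov_unscaled = mat(k, k, fill::zeros);
  }

  return Rcpp::List::create(
      Rcpp::Named("lambda") = best_lam, Rcpp::Named("loglik") = ll,
      Rcpp::Named("beta") = beta, Rcpp::Named("sigma2") = s2,
      Rcpp::Named("cov_unscaled") = cov_unscaled,
      Rcpp::Named("grid_loglik") = grid_ll,
      Rcpp::Named("degenerate") = degenerate);
}
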
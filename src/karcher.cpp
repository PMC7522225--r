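// Fast spherical averaging for square-root transformed densities.
//
// Columns of H are SRT values on a shared uniform grid; w holds the
// trapezoidal quadrature weights, so the discrete inner product
// dot(w % a, b) approximates the L2 inner product on [0, 1].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double wdot(const vec& w, const vec& a, const vec& b) {
  return dot(w % a, b);
}

static inline double clip_cos(double c) {
  return std::min(1.0, std::max(-1.0, c));
}

// Gradient iteration for the Karcher mean on the unit Hilbert sphere,
// started at the normalised extrinsic (pointwise) average.
static vec karcher_iterate(const mat& H, const vec& w, double step,
                           double tol, int max_iter, int& iters,
                           double& gnorm, bool& conv) {
  const unsigned int n = H.n_cols;
  vec mu = mean(H, 1);
  mu /= std::sqrt(wdot(w, mu, mu));
  gnorm = datum::inf;
  conv = false;
  iters = 0;
  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    vec wm = w % mu;
    rowvec ip = wm.t() * H;
    vec vbar(H.n_rows, fill::zeros);
    for (unsigned int i = 0; i < n; ++i) {
      double c = clip_cos(ip(i));
      double th = std::acos(c);
      if (th > 1e-9) vbar += (th / std::sin(th)) * (H.col(i) - c * mu);
    }
    vbar /= (double)n;
    gnorm = std::sqrt(wdot(w, vbar, vbar));
    if (gnorm < tol) { conv = true; break; }
    vec v = step * vbar;
    double nv = std::sqrt(wdot(w, v, v));
    if (nv > 1e-12) {
      mu = std::cos(nv) * mu + std::sin(nv) * (v / nv);
      mu /= std::sqrt(wdot(w, mu, mu));
    }
  }
  return mu;
}

// [[Rcpp::export]]
Rcpp::List karcher_mean_core(const arma::mat& H, const arma::vec& w,
                             double step, double tol, int max_iter) {
  int iters; double gnorm; bool conv;
  vec mu = karcher_iterate(H, w, step, tol, max_iter, iters, gnorm, conv);
  return Rcpp::List::create(
    Rcpp::Named("mean") = mu,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("gradient_norm") = gnorm,
    Rcpp::Named("converged") = conv);
}

// Geodesic distance between the Karcher means of the two label groups for
// every permutation (columns of `labels`, entries 0/1).
// [[Rcpp::export]]
arma::vec perm_null_core(const arma::mat& H, const arma::vec& w,
                         const arma::imat& labels, double step, double tol,
                         int max_iter) {
  const unsigned int n_perm = labels.n_cols;
  vec out(n_perm);
  int it; double g; bool cv;
  for (unsigned int k = 0; k < n_perm; ++k) {
    uvec g1 = find(labels.col(k) == 1);
    uvec g0 = find(labels.col(k) == 0);
    vec m0 = karcher_iterate(H.cols(g0), w, step, tol, max_iter, it, g, cv);
    vec m1 = karcher_iterate(H.cols(g1), w, step, tol, max_iter, it, g, cv);
    out(k) = std::acos(clip_cos(wdot(w, m0, m1)));
  }
  return out;
}
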
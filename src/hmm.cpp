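// Log-domain / scaled HMM recursions: forward filter backward sample (for
// Gibbs sweeps), Viterbi, and forward-backward smoothing. Emission input is
// a T x L log-likelihood matrix; scaling constants keep everything finite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Normalised emission weights per row: e[t,] = exp(ll[t,] - max(ll[t,])),
// with the row maxima returned for log-likelihood bookkeeping.
static arma::mat emission_weights(const arma::mat& loglik, arma::vec& rowmax) {
  arma::mat e(loglik.n_rows, loglik.n_cols);
  rowmax.set_size(loglik.n_rows);
  for (arma::uword t = 0; t < loglik.n_rows; ++t) {
    double m = loglik.row(t).max();
    rowmax(t) = m;
    e.row(t) = arma::exp(loglik.row(t) - m);
  }
  return e;
}

// Forward-filter backward-sample one state path. Uses R's RNG so draws are
// governed by set.seed() on the R side. Returns 1-based states.
// [[Rcpp::export]]
IntegerVector ffbs_cpp(const arma::mat& loglik, const arma::mat& P,
                       const arma::vec& pi0) {
  const arma::uword T = loglik.n_rows, L = loglik.n_cols;
  arma::vec rowmax;
  arma::mat e = emission_weights(loglik, rowmax);
  arma::mat alpha(T, L);
  arma::rowvec a = pi0.t() % e.row(0);
  a /= arma::accu(a);
  alpha.row(0) = a;
  for (arma::uword t = 1; t < T; ++t) {
    a = (alpha.row(t - 1) * P) % e.row(t);
    double s = arma::accu(a);
    if (s <= 0) { a.fill(1.0 / L); s = 1.0; }
    alpha.row(t) = a / s;
  }
  IntegerVector path(T);
  arma::rowvec w = alpha.row(T - 1);
  double u = R::runif(0.0, 1.0) * arma::accu(w);
  arma::uword s = 0; double acc = 0;
  for (arma::uword j = 0; j < L; ++j) { acc += w(j); if (u <= acc) { s = j; break; } }
  path[T - 1] = s + 1;
  for (arma::uword t = T - 1; t-- > 0; ) {
    w = alpha.row(t) % P.col(s).t();
    double tot = arma::accu(w);
    if (tot <= 0) { w = alpha.row(t); tot = arma::accu(w); }
    u = R::runif(0.0, 1.0) * tot;
    acc = 0; s = 0;
    for (arma::uword j = 0; j < L; ++j) { acc += w(j); if (u <= acc) { s = j; break; } }
    path[t] = s + 1;
  }
  return path;
}

// Max-product decoding in the log domain. Ties break to the lowest state.
// [[Rcpp::export]]
List viterbi_cpp(const arma::mat& loglik, const arma::mat& logP,
                 const arma::vec& logpi0) {
  const arma::uword T = loglik.n_rows, L = loglik.n_cols;
  arma::mat delta(T, L);
  arma::umat psi(T, L, arma::fill::zeros);
  delta.row(0) = logpi0.t() + loglik.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < L; ++j) {
      double best = -arma::datum::inf; arma::uword arg = 0;
      for (arma::uword i = 0; i < L; ++i) {
        double v = delta(t - 1, i) + logP(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + loglik(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  arma::uword s = delta.row(T - 1).index_max();
  double logprob = delta(T - 1, s);
  path[T - 1] = s + 1;
  for (arma::uword t = T - 1; t-- > 0; ) {
    s = psi(t + 1, s);
    path[t] = s + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = logprob);
}

// Scaled forward-backward smoothing: gamma[t,j] = p(S_t = j | y_{1:T}),
// plus the data log-likelihood.
// [[Rcpp::export]]
List forward_backward_cpp(const arma::mat& loglik, const arma::mat& P,
                          const arma::vec& pi0) {
  const arma::uword T = loglik.n_rows, L = loglik.n_cols;
  arma::vec rowmax;
  arma::mat e = emission_weights(loglik, rowmax);
  arma::mat alpha(T, L), beta(T, L);
  arma::vec cs(T);
  arma::rowvec a = pi0.t() % e.row(0);
  cs(0) = arma::accu(a);
  alpha.row(0) = a / cs(0);
  for (arma::uword t = 1; t < T; ++t) {
    a = (alpha.row(t - 1) * P) % e.row(t);
    cs(t) = arma::accu(a);
    if (cs(t) <= 0) { a.fill(1.0 / L); cs(t) = 1.0; }
    alpha.row(t) = a / cs(t);
  }
  beta.row(T - 1).fill(1.0);
  for (arma::uword t = T - 1; t-- > 0; ) {
    arma::rowvec b = (beta.row(t + 1) % e.row(t + 1)) * P.t();
    beta.row(t) = b / cs(t + 1);
  }
  arma::mat gamma = alpha % beta;
  for (arma::uword t = 0; t < T; ++t) gamma.row(t) /= arma::accu(gamma.row(t));
  double ll = arma::accu(arma::log(cs)) + arma::accu(rowmax);
  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}
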
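// Felsenstein pruning for k-state continuous-time Markov chains on trees.
// Edge matrix must be in postorder (children before parents). Tip partial
// likelihoods allow ambiguity (rows need not be one-hot).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-edge transition probability matrices P(t) = expm(Q t), computed via
// eigendecomposition with scaling-and-squaring fallback for defective Q.
static cube edge_probs(const mat& Q, const vec& elen) {
  const uword k = Q.n_rows, ne = elen.n_elem;
  cube P(k, k, ne);
  cx_vec eval;
  cx_mat evec;
  bool ok = eig_gen(eval, evec, Q);
  cx_mat evinv;
  if (ok) {
    ok = inv(evinv, evec);
    if (ok) {
      // reject near-defective decompositions
      double cnd = cond(evec);
      if (!std::isfinite(cnd) || cnd > 1e8) ok = false;
    }
  }
  for (uword e = 0; e < ne; ++e) {
    mat Pe;
    if (ok) {
      cx_mat D = diagmat(exp(eval * elen(e)));
      Pe = real(evec * D * evinv);
    } else {
      Pe = expmat(Q * elen(e));
    }
    Pe.elem(find(Pe < 0)).zeros();
    // renormalize rows against round-off
    Pe.each_col([](vec&) {});
    for (uword r = 0; r < k; ++r) {
      double s = accu(Pe.row(r));
      if (s > 0) Pe.row(r) /= s;
    }
    P.slice(e) = Pe;
  }
  return P;
}

// [[Rcpp::export]]
Rcpp::List mk_partials_cpp(const arma::imat& edge, const arma::vec& elen,
                           int n_tip, int n_node, const arma::mat& tipL,
                           const arma::mat& Q, const arma::vec& root_prior,
                           bool keep_P = false) {
  const int k = Q.n_rows;
  const int ntot = n_tip + n_node;
  cube P = edge_probs(Q, elen);
  mat part(ntot, k, fill::ones);
  vec logsc(ntot, fill::zeros);
  for (int i = 0; i < n_tip; ++i) part.row(i) = tipL.row(i);
  // postorder sweep: combine child messages into parents
  for (uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    rowvec msg = part.row(ch) * P.slice(e).t(); // msg[s] = sum_c P[s,c] L[c]
    part.row(par) %= msg;
    logsc(par) += logsc(ch);
    double m = part.row(par).max();
    if (m <= 0) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf);
    }
    part.row(par) /= m;
    logsc(par) += std::log(m);
  }
  int root = edge(edge.n_rows - 1, 0) - 1;
  double lik = dot(part.row(root).t(), root_prior);
  double ll = std::log(lik) + logsc(root);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("partials") = part,
    Rcpp::Named("root") = root + 1);
  if (keep_P) out["P"] = P;
  return out;
}

// [[Rcpp::export]]
double mk_loglik_cpp(const arma::imat& edge, const arma::vec& elen,
                     int n_tip, int n_node, const arma::mat& tipL,
                     const arma::mat& Q, const arma::vec& root_prior) {
  Rcpp::List r = mk_partials_cpp(edge, elen, n_tip, n_node, tipL, Q, root_prior, false);
  return Rcpp::as<double>(r["loglik"]);
}
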
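// Block coordinate-descent graphical lasso.
//
// Maximizes  log det K - trace(S K) - lambda * sum_{i != j} |k_ij|
// (diagonal unpenalized) by cycling over columns of the working
// covariance W and solving each conditional problem as an L1-penalized
// regression by coordinate descent, with warm starts along a lambda path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// one coordinate-descent lasso solve:
//   min_b 0.5 b' W11 b - s12' b + lambda * |b|_1
static void lasso_cd(const mat& W11, const vec& s12, double lambda,
                     vec& beta, double tol, int maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword k = 0; k < q; ++k) {
      double old = beta(k);
      // partial residual: s12_k - sum_{l != k} W11(k,l) beta_l
      double r = s12(k) - dot(W11.row(k), beta) + W11(k, k) * old;
      double bnew;
      if (r > lambda)       bnew = (r - lambda) / W11(k, k);
      else if (r < -lambda) bnew = (r + lambda) / W11(k, k);
      else                  bnew = 0.0;
      beta(k) = bnew;
      double d = std::abs(bnew - old);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) break;
  }
}

// single glasso fit; W and B (p-1 x p beta store) are updated in place
static int glasso_one(const mat& S, double lambda, mat& W, mat& B,
                      double tol, int maxit_outer, int maxit_inner) {
  const uword p = S.n_rows;
  // scale for convergence: average absolute off-diagonal of S
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) sbar += std::abs(S(i, j));
  sbar /= (double)(p * (p - 1));
  if (sbar <= 0.0) sbar = 1.0;
  const double thr = tol * sbar;
  const double inner_tol = 0.1 * thr;

  int iters = -1;
  for (int it = 0; it < maxit_outer; ++it) {
    double maxchange = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);
      lasso_cd(W11, s12, lambda, beta, inner_tol, maxit_inner);
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > maxchange) maxchange = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (maxchange < thr) { iters = it + 1; break; }
  }
  return iters; // -1 => not converged
}

static mat precision_from(const mat& S, const mat& W, const mat& B) {
  const uword p = S.n_rows;
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    vec beta = B.col(j);
    vec w12 = W(idx, uvec{j});
    double k22 = 1.0 / (W(j, j) - dot(w12, beta));
    K(j, j) = k22;
    for (uword k = 0; k < p - 1; ++k) K(idx(k), j) = -beta(k) * k22;
  }
  return 0.5 * (K + K.t());
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, double tol,
                      int maxit_outer, int maxit_inner) {
  mat W = S; // diagonal unpenalized: W keeps diag(S)
  mat B(S.n_rows - 1, S.n_cols, fill::zeros);
  int iters = glasso_one(S, lambda, W, B, tol, maxit_outer, maxit_inner);
  mat K = precision_from(S, W, B);
  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("converged") = iters > 0);
}

// lambda path with warm starts, decreasing lambda expected
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit_outer, int maxit_inner) {
  const uword p = S.n_rows, m = lambdas.n_elem;
  mat W = S;
  mat B(p - 1, p, fill::zeros);
  cube Ks(p, p, m);
  Rcpp::IntegerVector iters(m);
  Rcpp::LogicalVector conv(m);
  for (uword l = 0; l < m; ++l) {
    int it = glasso_one(S, lambdas(l), W, B, tol, maxit_outer, maxit_inner);
    iters[l] = it;
    conv[l] = it > 0;
    Ks.slice(l) = precision_from(S, W, B);
  }
  return Rcpp::List::create(Rcpp::Named("K") = Ks,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("converged") = conv);
}
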
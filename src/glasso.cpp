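// Sparse inverse-covariance estimation by block coordinate descent
// (Friedman-style graphical lasso). Off-diagonal entries only are
// penalized, so diag(W) == diag(S) throughout; this is the convention
// used throughout the psychometric-network literature.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso subproblem: min_b 0.5 b'Vb - s'b + rho * ||b||_1
// via cyclic coordinate descent, warm-started at b.
static void lasso_cd(const mat& V, const vec& s, double rho, vec& b,
                     int maxit, double tol) {
  const uword q = s.n_elem;
  vec Vb = V * b;  // maintained incrementally
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (uword k = 0; k < q; ++k) {
      double bk_old = b(k);
      double grad_k = Vb(k) - V(k, k) * bk_old;  // sum_{l != k} V_kl b_l
      double bk = soft(s(k) - grad_k, rho) / V(k, k);
      if (bk != bk_old) {
        b(k) = bk;
        Vb += (bk - bk_old) * V.col(k);
        delta = std::max(delta, std::fabs(bk - bk_old));
      }
    }
    if (delta < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      Rcpp::Nullable<Rcpp::NumericMatrix> beta_init = R_NilValue,
                      int maxit = 200, double tol = 1e-6) {
  const uword p = S.n_rows;
  mat W = S;                  // diagonal unpenalized: w_jj = s_jj
  mat Beta(p, p, fill::zeros);
  if (beta_init.isNotNull()) {
    Beta = Rcpp::as<mat>(beta_init.get());
  }

  double off_mean = 0.0;
  if (p > 1) {
    off_mean = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(p * (p - 1));
  }
  if (off_mean <= 0) off_mean = 1.0;
  const double wtol = tol * off_mean;

  uvec all = regspace<uvec>(0, p - 1);
  for (int sweep = 0; sweep < maxit; ++sweep) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec b = Beta.col(j); b = b.elem(idx);
      lasso_cd(W11, s12, rho, b, 500, tol * 0.1);
      vec w12 = W11 * b;
      for (uword k = 0; k < idx.n_elem; ++k) {
        double change = std::fabs(W(idx(k), j) - w12(k));
        if (change > max_change) max_change = change;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        Beta(idx(k), j) = b(k);
      }
    }
    if (max_change < wtol) break;
  }

  // Recover the precision matrix from the final regression coefficients.
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = Beta.col(j); b = b.elem(idx);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = theta_jj;
    for (uword k = 0; k < idx.n_elem; ++k) {
      Theta(idx(k), j) = -b(k) * theta_jj;
    }
  }
  // Enforce exact symmetry and a symmetric zero pattern: an edge is
  // present only when both regressions kept it.
  for (uword i = 0; i < p; ++i) {
    for (uword j = i + 1; j < p; ++j) {
      if (Beta(i, j) == 0.0 || Beta(j, i) == 0.0) {
        Theta(i, j) = Theta(j, i) = 0.0;
      } else {
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = Theta(j, i) = v;
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("wi") = Theta,
                            Rcpp::Named("beta") = Beta);
}
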
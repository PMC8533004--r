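// Block coordinate-descent graphical lasso with an elementwise penalty
// matrix. Each column subproblem is a lasso with per-coefficient penalties,
// solved by coordinate descent (warm-started across sweeps).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// penalized log-likelihood: log det Theta - tr(S Theta) - sum rho |Theta|
// (rho has zero diagonal, so only off-diagonal entries are penalized)
static double objective(const mat& Theta, const mat& S, const mat& Rho,
                        bool& ok) {
  mat Ts = 0.5 * (Theta + Theta.t());
  double ldet, sign;
  ok = log_det(ldet, sign, Ts);
  if (!ok || sign <= 0.0) { ok = false; return -datum::inf; }
  return ldet - accu(S % Ts) - accu(Rho % abs(Ts));
}

static mat assemble_theta(const mat& W, const mat& Beta) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    // theta_jj = 1 / (w_jj - w12' beta_j); theta_.j = -beta_j * theta_jj
    double dot_wb = 0.0;
    for (uword k = 0; k < p; ++k)
      if (k != j) dot_wb += W(k, j) * Beta(k, j);
    double tjj = 1.0 / (W(j, j) - dot_wb);
    Theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -Beta(k, j) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, const arma::mat& Rho, double tol,
                     int max_iter, double inner_tol, int inner_max) {
  const uword p = S.n_rows;
  mat W = S;
  mat Beta(p, p, fill::zeros);

  std::vector<double> trace;
  bool ok = false;
  double obj = -datum::inf;
  bool converged = false;
  int sweeps = 0;

  for (int it = 0; it < max_iter; ++it) {
    for (uword j = 0; j < p; ++j) {
      // partition: solve min 1/2 b' W11 b - s12' b + sum rho12 |b|
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec r12 = Rho.col(j); r12 = r12.elem(idx);
      vec beta = Beta.col(j); beta = beta.elem(idx);

      vec v = W11 * beta;              // maintained = W11 %*% beta
      for (int ii = 0; ii < inner_max; ++ii) {
        double maxdiff = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double wkk = W11(k, k);
          if (wkk <= 0) continue;      // degenerate variance: keep at 0
          double g = s12(k) - (v(k) - wkk * beta(k));
          double bnew = soft(g, r12(k)) / wkk;
          double d = bnew - beta(k);
          if (d != 0.0) {
            v += W11.col(k) * d;
            beta(k) = bnew;
            double ad = std::abs(d);
            if (ad > maxdiff) maxdiff = ad;
          }
        }
        if (maxdiff < inner_tol) break;
      }
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        Beta(idx(k), j) = beta(k);
      }
    }
    ++sweeps;
    mat Theta = assemble_theta(W, Beta);
    double new_obj = objective(Theta, S, Rho, ok);
    trace.push_back(new_obj);
    if (ok && std::isfinite(obj)) {
      double rel = std::abs(new_obj - obj) /
                   std::max(std::abs(obj), 1e-12);
      if (rel < tol) { converged = true; obj = new_obj; break; }
    }
    obj = new_obj;
  }

  mat Theta = assemble_theta(W, Beta);
  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("W") = W,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("sweeps") = sweeps);
}
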
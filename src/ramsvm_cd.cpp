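// Cyclic coordinate descent for the box-constrained dual QPs of the
// weighted angle-based multicategory SVM (RAMSVM).
//
// Linear dual (records i = 1..m, groups j = 1..K, labels c_i, weights w_i,
// covariates x_i already augmented with a leading 1):
//
//   min_a  (1/(2 n lambda)) sum_k || u_k ||^2
//          - sum_i [ (K-1) a_{i,c_i} + sum_{j != c_i} a_{ij} ]
//   u_k    = sum_i v_{ik} x_i,
//   v_{ik} = a_{i,c_i} W_{c_i,k} - sum_{j != c_i} a_{ij} W_{jk}
//   s.t.   0 <= a_{ij} <= w_i * (gamma if j = c_i else 1 - gamma)
//
// Kernel dual adds the intercept quadratic and replaces the covariate
// Gram structure:
//
//   min_a  (1/(2 n lambda)) [ sum_k v_k' G v_k + sum_k (1'v_k)^2 ] - (linear)
//
// Both are strictly convex in each coordinate, so every single-coordinate
// update is an exact 1-D quadratic minimization clipped to the box; the
// objective is non-increasing across updates.  Convergence is declared when
// either the largest projected-gradient (box KKT) residual or the largest
// coordinate change seen in a full sweep falls below `tol`.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Per-group signed code coefficients for a record with label c:
//   s_{jk} = W_{c,k} if j == c, else -W_{jk}
inline arma::rowvec coef_row(const arma::mat& W, int c, int j) {
  if (j == c) return W.row(c);
  return -W.row(j);
}

inline double box_clip(double x, double up) {
  if (x < 0.0) return 0.0;
  if (x > up) return up;
  return x;
}

} // namespace

// [[Rcpp::export(name = ".cd_ramsvm_linear")]]
List cd_ramsvm_linear(const arma::mat& X,       // m x p (augmented)
                      const arma::ivec& label,  // 1..K
                      const arma::vec& weight,  // >= 0
                      const arma::mat& W,       // K x (K-1)
                      double n_eff,
                      double lambda,
                      double gamma,
                      double tol,
                      int max_sweeps) {
  const int m = X.n_rows;
  const int p = X.n_cols;
  const int K = W.n_rows;
  const int Km1 = K - 1;
  const double scale = 1.0 / (n_eff * lambda);

  arma::mat alpha(m, K, arma::fill::zeros);
  arma::mat upper(m, K);
  arma::vec lin(K); // linear dual coefficients per column, filled per record
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < K; ++j) {
      upper(i, j) = weight(i) * ((j == label(i) - 1) ? gamma : (1.0 - gamma));
    }
  }

  arma::mat U(p, Km1, arma::fill::zeros); // u_k columns
  arma::vec xnorm2(m);
  for (int i = 0; i < m; ++i) xnorm2(i) = arma::dot(X.row(i), X.row(i));

  std::vector<double> obj_trace;
  obj_trace.reserve(max_sweeps + 1);
  auto objective = [&]() {
    double quad = 0.5 * scale * arma::accu(U % U);
    double l = 0.0;
    for (int i = 0; i < m; ++i) {
      const int c = label(i) - 1;
      for (int j = 0; j < K; ++j)
        l += alpha(i, j) * ((j == c) ? double(Km1) : 1.0);
    }
    return quad - l;
  };
  obj_trace.push_back(objective());

  bool converged = false;
  int sweeps = 0;
  double max_kkt = R_PosInf;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double sweep_kkt = 0.0;
    double sweep_delta = 0.0;
    for (int i = 0; i < m; ++i) {
      const int c = label(i) - 1;
      arma::rowvec xu = X.row(i) * U;       // x_i' u_k, length K-1
      arma::rowvec dv(Km1, arma::fill::zeros);
      const double h = scale * xnorm2(i);   // per-coordinate Hessian
      for (int j = 0; j < K; ++j) {
        const double up = upper(i, j);
        if (up <= 0.0) continue;
        const arma::rowvec s = coef_row(W, c, j);
        const double lcoef = (j == c) ? double(Km1) : 1.0;
        const double a_old = alpha(i, j);
        double a_new;
        double viol;
        if (h > 0.0) {
          const double grad = scale * arma::dot(s, xu) - lcoef;
          a_new = box_clip(a_old - grad / h, up);
          viol = h * std::abs(a_old - a_new);
        } else { // degenerate zero covariate: objective linear, slope -lcoef
          a_new = up;
          viol = (a_old < up) ? lcoef : 0.0;
        }
        if (viol > sweep_kkt) sweep_kkt = viol;
        const double d = a_new - a_old;
        if (std::abs(d) > sweep_delta) sweep_delta = std::abs(d);
        if (d != 0.0) {
          alpha(i, j) = a_new;
          xu += (d * xnorm2(i)) * s;
          dv += d * s;
        }
      }
      if (arma::any(arma::abs(dv) > 0.0)) U += X.row(i).t() * dv;
    }
    obj_trace.push_back(objective());
    sweeps = sweep + 1;
    max_kkt = sweep_kkt;
    if (sweep_kkt <= tol || sweep_delta <= tol) { converged = true; break; }
  }

  // primal recovery: beta_k = u_k / (n lambda)
  arma::mat B = (U * scale).t(); // (K-1) x p

  return List::create(
      _["alpha"] = alpha,
      _["upper"] = upper,
      _["objective"] = obj_trace.back(),
      _["objective_trace"] = obj_trace,
      _["B"] = B,
      _["sweeps"] = sweeps,
      _["max_kkt"] = max_kkt,
      _["converged"] = converged);
}

// [[Rcpp::export(name = ".cd_ramsvm_kernel")]]
List cd_ramsvm_kernel(const arma::mat& G,       // m x m Gram matrix
                      const arma::ivec& label,
                      const arma::vec& weight,
                      const arma::mat& W,
                      double n_eff,
                      double lambda,
                      double gamma,
                      double tol,
                      int max_sweeps) {
  const int m = G.n_rows;
  const int K = W.n_rows;
  const int Km1 = K - 1;
  const double scale = 1.0 / (n_eff * lambda);

  arma::mat alpha(m, K, arma::fill::zeros);
  arma::mat upper(m, K);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < K; ++j)
      upper(i, j) = weight(i) * ((j == label(i) - 1) ? gamma : (1.0 - gamma));

  arma::mat V(m, Km1, arma::fill::zeros);  // v_k columns
  arma::mat GV(m, Km1, arma::fill::zeros); // G v_k
  arma::rowvec S(Km1, arma::fill::zeros);  // 1' v_k

  std::vector<double> obj_trace;
  obj_trace.reserve(max_sweeps + 1);
  auto objective = [&]() {
    double quad = 0.5 * scale * (arma::accu(V % GV) + arma::dot(S, S));
    double l = 0.0;
    for (int i = 0; i < m; ++i) {
      const int c = label(i) - 1;
      for (int j = 0; j < K; ++j)
        l += alpha(i, j) * ((j == c) ? double(Km1) : 1.0);
    }
    return quad - l;
  };
  obj_trace.push_back(objective());

  bool converged = false;
  int sweeps = 0;
  double max_kkt = R_PosInf;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double sweep_kkt = 0.0;
    double sweep_delta = 0.0;
    for (int i = 0; i < m; ++i) {
      const int c = label(i) - 1;
      const double h = scale * (G(i, i) + 1.0);
      for (int j = 0; j < K; ++j) {
        const double up = upper(i, j);
        if (up <= 0.0) continue;
        const arma::rowvec s = coef_row(W, c, j);
        const double lcoef = (j == c) ? double(Km1) : 1.0;
        const double a_old = alpha(i, j);
        const double grad = scale * (arma::dot(s, GV.row(i)) + arma::dot(s, S)) - lcoef;
        double a_new, viol;
        if (h > 0.0) {
          a_new = box_clip(a_old - grad / h, up);
          viol = h * std::abs(a_old - a_new);
        } else {
          a_new = (grad < 0.0) ? up : 0.0;
          viol = std::abs(a_new - a_old) > 0.0 ? std::abs(grad) : 0.0;
        }
        if (viol > sweep_kkt) sweep_kkt = viol;
        const double d = a_new - a_old;
        if (std::abs(d) > sweep_delta) sweep_delta = std::abs(d);
        if (d != 0.0) {
          alpha(i, j) = a_new;
          V.row(i) += d * s;
          GV += G.col(i) * (d * s);
          S += d * s;
        }
      }
    }
    obj_trace.push_back(objective());
    sweeps = sweep + 1;
    max_kkt = sweep_kkt;
    if (sweep_kkt <= tol || sweep_delta <= tol) { converged = true; break; }
  }

  // primal recovery: theta_k = G^{-1} (G v_k) / (n lambda) = v_k / (n lambda),
  // intercept theta_{k,0} = (1'v_k) / (n lambda)
  arma::mat Theta = V * scale;
  arma::rowvec theta0 = S * scale;

  return List::create(
      _["alpha"] = alpha,
      _["upper"] = upper,
      _["objective"] = obj_trace.back(),
      _["objective_trace"] = obj_trace,
      _["Theta"] = Theta,
      _["intercepts"] = theta0,
      _["sweeps"] = sweeps,
      _["max_kkt"] = max_kkt,
      _["converged"] = converged);
}
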
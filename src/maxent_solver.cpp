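#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Smooth part of the penalized maxent objective:
//   f(beta) = log sum_i exp(eta_i) - fbar' beta
// over the background rows of F (uniform base measure; the constant
// -log N is dropped). Returns f and fills logZ = logsumexp(eta).
static double smooth_obj(const mat& F, const vec& beta, const vec& fbar,
                         double& logZ, vec& eta) {
  eta = F * beta;
  double m = eta.max();
  logZ = m + std::log(accu(exp(eta - m)));
  return logZ - dot(fbar, beta);
}

static vec soft_threshold(const vec& x, const vec& t) {
  return sign(x) % max(abs(x) - t, zeros<vec>(x.n_elem));
}

// L1-penalized maximum-entropy fit by FISTA (accelerated proximal
// gradient) with backtracking line search and restart on objective
// increase. The objective is convex; convergence is declared when the
// relative change of the full objective drops below tol.
// [[Rcpp::export]]
Rcpp::List maxent_solve_cpp(const arma::mat& F, const arma::vec& fbar,
                            const arma::vec& lambda, double tol,
                            int max_iter, arma::vec beta_init) {
  const uword J = F.n_cols;
  vec beta = beta_init.n_elem == J ? beta_init : zeros<vec>(J);
  vec y = beta;
  vec eta;
  double logZ = 0.0;
  double t_mom = 1.0;
  double step = 1.0;
  double obj = smooth_obj(F, beta, fbar, logZ, eta) + dot(lambda, abs(beta));
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    vec eta_y;
    double logZ_y;
    double fy = smooth_obj(F, y, fbar, logZ_y, eta_y);
    vec p = exp(eta_y - logZ_y);
    vec grad = F.t() * p - fbar;

    // backtracking: quadratic upper bound check at the proximal point
    vec beta_new;
    step *= 1.3;  // allow recovery after conservative halvings
    for (;;) {
      beta_new = soft_threshold(y - step * grad, step * lambda);
      vec d = beta_new - y;
      double fnew = smooth_obj(F, beta_new, fbar, logZ, eta);
      if (fnew <= fy + dot(grad, d) + dot(d, d) / (2.0 * step) + 1e-12)
        break;
      step *= 0.5;
      if (step < 1e-14) break;
    }

    double obj_new = smooth_obj(F, beta_new, fbar, logZ, eta) +
                     dot(lambda, abs(beta_new));
    double t_new = (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom)) / 2.0;
    if (obj_new > obj) {          // restart momentum
      y = beta_new;
      t_mom = 1.0;
    } else {
      y = beta_new + ((t_mom - 1.0) / t_new) * (beta_new - beta);
      t_mom = t_new;
    }

    double rel = std::abs(obj - obj_new) / std::max(1.0, std::abs(obj_new));
    beta = beta_new;
    obj = obj_new;
    if (it > 1 && rel < tol) {
      converged = true;
      break;
    }
  }

  // final normalizer at beta
  smooth_obj(F, beta, fbar, logZ, eta);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("log_normalizer") = logZ,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
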
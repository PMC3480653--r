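#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// numerically stable log(1 + exp(x))
static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// penalized binomial log-likelihood: sum_i [y_i eta_i - log(1+e^eta_i)]
//   - lambda (1-alpha)/2 sum_pen beta_j^2 - lambda alpha sum_pen |beta_j|
static double penalized_objective(const std::vector<double>& eta,
                                  const double* y, int n,
                                  const std::vector<double>& beta,
                                  const double* penalty,
                                  double alpha, double lambda) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) ll += y[i] * eta[i] - log1p_exp(eta[i]);
  double l1 = 0.0, l2 = 0.0;
  const int p = (int)beta.size();
  for (int j = 0; j < p; ++j) {
    if (penalty[j] > 0.0) {
      l1 += std::fabs(beta[j]);
      l2 += beta[j] * beta[j];
    }
  }
  return ll - 0.5 * lambda * (1.0 - alpha) * l2 - lambda * alpha * l1;
}

// Core IRLS + cyclic coordinate descent solver.  X is column-major n x p.
// beta/eta are updated in place; returns sweeps used, sets converged flag and
// optionally records the objective after each outer iteration.
static int cd_core(const double* X, const double* y, const double* penalty,
                   int n, int p, double alpha, double lambda,
                   std::vector<double>& beta, std::vector<double>& eta,
                   double tol, int max_iter, bool& converged,
                   std::vector<double>* obj_path) {
  std::vector<double> prob(n), w(n), r(n), xwx(p), bw(p), beta_try(p), eta_try(n);
  double obj = penalized_objective(eta, y, n, beta, penalty, alpha, lambda);
  if (obj_path) obj_path->push_back(obj);
  const double lam_l1 = lambda * alpha;
  const double lam_l2 = lambda * (1.0 - alpha);
  converged = false;
  int sweeps = 0;

  while (sweeps < max_iter) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      if (pi < 1e-8) pi = 1e-8;
      if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
      prob[i] = pi;
      double wi = pi * (1.0 - pi);
      w[i] = (wi < 1e-9) ? 1e-9 : wi;
      r[i] = y[i] - pi;  // = w_i (z_i - eta_i)
    }
    for (int j = 0; j < p; ++j) {
      const double* xj = X + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
      xwx[j] = s;
    }

    // inner coordinate descent on the penalized weighted least squares
    bw = beta;
    int inner_guard = 0;
    while (sweeps < max_iter) {
      double maxdelta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double* xj = X + (size_t)j * n;
        double num = bw[j] * xwx[j];
        for (int i = 0; i < n; ++i) num += xj[i] * r[i];
        double bnew;
        if (penalty[j] > 0.0) {
          bnew = soft_threshold(num, lam_l1) / (xwx[j] + lam_l2);
        } else {
          bnew = num / xwx[j];
        }
        double d = bnew - bw[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= d * w[i] * xj[i];
          bw[j] = bnew;
          double ad = std::fabs(d);
          if (ad > maxdelta) maxdelta = ad;
        }
      }
      ++sweeps;
      ++inner_guard;
      if (maxdelta < tol || inner_guard >= 1000) break;
    }

    // step halving on the exact objective (outer monotonicity safeguard)
    double t = 1.0, obj_try = 0.0;
    for (int half = 0; half < 40; ++half) {
      for (int j = 0; j < p; ++j) beta_try[j] = beta[j] + t * (bw[j] - beta[j]);
      for (int i = 0; i < n; ++i) eta_try[i] = 0.0;
      for (int j = 0; j < p; ++j) {
        if (beta_try[j] == 0.0) continue;
        const double* xj = X + (size_t)j * n;
        for (int i = 0; i < n; ++i) eta_try[i] += xj[i] * beta_try[j];
      }
      obj_try = penalized_objective(eta_try, y, n, beta_try, penalty, alpha, lambda);
      if (obj_try >= obj - 1e-10) break;
      t *= 0.5;
      if (t < 1e-6) {  // no ascent possible: stay put
        beta_try = beta;
        for (int i = 0; i < n; ++i) eta_try[i] = eta[i];
        obj_try = obj;
        break;
      }
    }

    double delta_outer = 0.0;
    for (int j = 0; j < p; ++j) {
      double d = std::fabs(beta_try[j] - beta[j]);
      if (d > delta_outer) delta_outer = d;
    }
    beta = beta_try;
    eta = eta_try;
    obj = obj_try;
    if (obj_path) obj_path->push_back(obj);

    if (delta_outer < tol) {
      converged = true;
      break;
    }
  }
  return sweeps;
}

// Elastic-net penalized logistic regression by IRLS + cyclic coordinate
// descent on the working least-squares problem.  Columns with penalty[j] == 0
// (intercept, age) are unpenalized.  A step-halving safeguard on the exact
// penalized objective makes the outer iteration monotone.
// [[Rcpp::export]]
List enet_cd_fit(const NumericMatrix& X, const NumericVector& y,
                 const NumericVector& penalty, double alpha, double lambda,
                 NumericVector beta_init, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    if (beta[j] == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * beta[j];
  }
  std::vector<double> obj_path;
  bool converged = false;
  int sweeps = cd_core(REAL(X), REAL(y), REAL(penalty), n, p, alpha, lambda,
                       beta, eta, tol, max_iter, converged, &obj_path);
  return List::create(
      _["beta"] = NumericVector(beta.begin(), beta.end()),
      _["converged"] = converged,
      _["sweeps"] = sweeps,
      _["objective"] = obj_path.back(),
      _["objective_path"] = NumericVector(obj_path.begin(), obj_path.end()));
}

// Warm-started solution path over a descending lambda sequence (one alpha).
// Returns a p x L coefficient matrix plus per-lambda convergence flags.
// [[Rcpp::export]]
List enet_cd_path(const NumericMatrix& X, const NumericVector& y,
                  const NumericVector& penalty, double alpha,
                  const NumericVector& lambdas, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix betas(p, L);
  LogicalVector conv(L);
  std::vector<double> beta(p, 0.0), eta(n, 0.0);
  for (int l = 0; l < L; ++l) {
    bool converged = false;
    cd_core(REAL(X), REAL(y), REAL(penalty), n, p, alpha, lambdas[l],
            beta, eta, tol, max_iter, converged, nullptr);
    conv[l] = converged;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
  }
  return List::create(_["beta"] = betas, _["converged"] = conv);
}
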
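// Latent-variable computations for the ordinal factor model in the delta
// parameterization: latent response y*_j = lambda_j' eta + e_j with
// Var(y*_j) = 1, so P(y_j = c | eta) = Phi((tau_{c+1} - m)/s) -
// Phi((tau_c - m)/s), m = lambda_j' eta, s = residual sd.
//
// - qmc_loglik: marginal log-likelihood per respondent by averaging the
//   conditional likelihood over a supplied set of integration nodes
//   (randomized low-discrepancy points transformed in R).
// - map_scores: maximum a posteriori factor scores by per-respondent
//   Newton iteration with step halving.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double pnorm_std(double x) { return R::pnorm(x, 0, 1, 1, 0); }
static inline double dnorm_std(double x) { return R::dnorm(x, 0, 1, 0); }

// [[Rcpp::export(name = ".qmc_loglik_cpp")]]
NumericVector qmc_loglik_cpp(IntegerMatrix y, NumericMatrix lambda,
                             List taus, NumericVector resid_sd,
                             NumericMatrix nodes) {
  int n = y.nrow(), J = y.ncol(), F = lambda.ncol(), Q = nodes.nrow();
  NumericMatrix acc(n, Q);  // log conditional likelihood per person x node
  for (int j = 0; j < J; ++j) {
    NumericVector tau = taus[j];
    int K = tau.size() + 1;
    double s = resid_sd[j];
    // log category probabilities at each node
    NumericMatrix logp(K, Q);
    for (int q = 0; q < Q; ++q) {
      double m = 0.0;
      for (int f = 0; f < F; ++f) m += lambda(j, f) * nodes(q, f);
      double prev = 0.0;
      for (int c = 0; c < K; ++c) {
        double upper = (c == K - 1) ? 1.0 : pnorm_std((tau[c] - m) / s);
        double p = upper - prev;
        prev = upper;
        logp(c, q) = log(p > 1e-300 ? p : 1e-300);
      }
    }
    const int* yj = &y(0, j);
    const double* lp = &logp(0, 0);
    double* ac = &acc(0, 0);
    for (int q = 0; q < Q; ++q) {
      const double* lpq = lp + (size_t)q * K;
      double* acq = ac + (size_t)q * n;
      for (int i = 0; i < n; ++i) {
        int c = yj[i];
        if (c >= 0) acq[i] += lpq[c];
      }
    }
  }
  NumericVector out(n);
  double logQ = log((double)Q);
  const double* ac = &acc(0, 0);
  std::vector<double> mx(n, R_NegInf), sm(n, 0.0);
  for (int q = 0; q < Q; ++q) {
    const double* acq = ac + (size_t)q * n;
    for (int i = 0; i < n; ++i) if (acq[i] > mx[i]) mx[i] = acq[i];
  }
  for (int q = 0; q < Q; ++q) {
    const double* acq = ac + (size_t)q * n;
    for (int i = 0; i < n; ++i) sm[i] += exp(acq[i] - mx[i]);
  }
  for (int i = 0; i < n; ++i) out[i] = mx[i] + log(sm[i]) - logQ;
  return out;
}

// solve A x = b for small symmetric A (Gaussian elimination, partial pivot)
static bool solve_small(std::vector<double>& A, std::vector<double>& b,
                        int F) {
  for (int k = 0; k < F; ++k) {
    int piv = k;
    for (int r = k + 1; r < F; ++r)
      if (fabs(A[r * F + k]) > fabs(A[piv * F + k])) piv = r;
    if (fabs(A[piv * F + k]) < 1e-12) return false;
    if (piv != k) {
      for (int c = 0; c < F; ++c) std::swap(A[k * F + c], A[piv * F + c]);
      std::swap(b[k], b[piv]);
    }
    for (int r = k + 1; r < F; ++r) {
      double f = A[r * F + k] / A[k * F + k];
      for (int c = k; c < F; ++c) A[r * F + c] -= f * A[k * F + c];
      b[r] -= f * b[k];
    }
  }
  for (int k = F - 1; k >= 0; --k) {
    double s = b[k];
    for (int c = k + 1; c < F; ++c) s -= A[k * F + c] * b[c];
    b[k] = s / A[k * F + k];
  }
  return true;
}

// negative log posterior (up to a constant) and its gradient/Hessian
static double nlp_eval(const IntegerMatrix& y, int i,
                       const NumericMatrix& lambda, const List& taus,
                       const NumericVector& resid_sd,
                       const NumericMatrix& phi_inv,
                       const std::vector<double>& eta,
                       std::vector<double>* grad,
                       std::vector<double>* hess) {
  int J = y.ncol(), F = lambda.ncol();
  double nlp = 0.0;
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);
  if (hess) std::fill(hess->begin(), hess->end(), 0.0);
  for (int j = 0; j < J; ++j) {
    int c = y(i, j);
    if (c < 0) continue;
    NumericVector tau = taus[j];
    int K = tau.size() + 1;
    double s = resid_sd[j];
    double m = 0.0;
    for (int f = 0; f < F; ++f) m += lambda(j, f) * eta[f];
    double u1 = (c == 0) ? R_NegInf : (tau[c - 1] - m) / s;
    double u2 = (c == K - 1) ? R_PosInf : (tau[c] - m) / s;
    double F1 = (c == 0) ? 0.0 : pnorm_std(u1);
    double F2 = (c == K - 1) ? 1.0 : pnorm_std(u2);
    double p = F2 - F1;
    if (p < 1e-300) p = 1e-300;
    nlp -= log(p);
    if (grad || hess) {
      double d1 = (c == 0) ? 0.0 : dnorm_std(u1);
      double d2 = (c == K - 1) ? 0.0 : dnorm_std(u2);
      double G = -(d2 - d1) / (s * p);   // dlogp/dm
      double t1 = (c == K - 1) ? 0.0 : u2 * d2;
      double t0 = (c == 0) ? 0.0 : u1 * d1;
      double H = -(t1 - t0) / (s * s * p) - G * G;  // d2logp/dm2
      for (int f = 0; f < F; ++f) {
        if (grad) (*grad)[f] -= G * lambda(j, f);
        if (hess)
          for (int g = 0; g <= f; ++g)
            (*hess)[f * F + g] -= H * lambda(j, f) * lambda(j, g);
      }
    }
  }
  // prior: 0.5 eta' Phi^{-1} eta
  for (int f = 0; f < F; ++f) {
    double pf = 0.0;
    for (int g = 0; g < F; ++g) pf += phi_inv(f, g) * eta[g];
    nlp += 0.5 * eta[f] * pf;
    if (grad) (*grad)[f] += pf;
    if (hess)
      for (int g = 0; g <= f; ++g) (*hess)[f * F + g] += phi_inv(f, g);
  }
  if (hess)
    for (int f = 0; f < F; ++f)
      for (int g = f + 1; g < F; ++g) (*hess)[f * F + g] = (*hess)[g * F + f];
  return nlp;
}

// [[Rcpp::export(name = ".map_scores_cpp")]]
List map_scores_cpp(IntegerMatrix y, NumericMatrix lambda, List taus,
                    NumericVector resid_sd, NumericMatrix phi_inv,
                    int max_iter, double tol) {
  int n = y.nrow(), F = lambda.ncol();
  NumericMatrix out(n, F);
  LogicalVector conv(n);
  std::vector<double> eta(F), grad(F), hess(F * F), A(F * F), step(F);
  for (int i = 0; i < n; ++i) {
    bool any_obs = false;
    for (int j = 0; j < y.ncol(); ++j) if (y(i, j) >= 0) any_obs = true;
    if (!any_obs) {
      for (int f = 0; f < F; ++f) out(i, f) = NA_REAL;
      conv[i] = false;
      continue;
    }
    std::fill(eta.begin(), eta.end(), 0.0);
    double f0 = nlp_eval(y, i, lambda, taus, resid_sd, phi_inv, eta,
                         &grad, &hess);
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      double gn = 0.0;
      for (int f = 0; f < F; ++f) gn += grad[f] * grad[f];
      if (sqrt(gn) < tol) { ok = true; break; }
      A = hess;
      step = grad;
      if (!solve_small(A, step, F)) {
        // fall back to gradient descent step
        for (int f = 0; f < F; ++f) step[f] = grad[f];
      }
      double alpha = 1.0;
      std::vector<double> trial(F);
      bool improved = false;
      for (int h = 0; h < 30; ++h) {
        for (int f = 0; f < F; ++f) trial[f] = eta[f] - alpha * step[f];
        double f1 = nlp_eval(y, i, lambda, taus, resid_sd, phi_inv, trial,
                             NULL, NULL);
        if (f1 < f0) {
          eta = trial;
          f0 = f1;
          improved = true;
          break;
        }
        alpha *= 0.5;
      }
      if (!improved) { ok = true; break; }  // at a numerical optimum
      nlp_eval(y, i, lambda, taus, resid_sd, phi_inv, eta, &grad, &hess);
    }
    for (int f = 0; f < F; ++f) out(i, f) = eta[f];
    conv[i] = ok;
  }
  return List::create(_["scores"] = out, _["converged"] = conv);
}
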
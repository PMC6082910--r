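// Two-stage polychoric correlation machinery.
//
// Stage 1 (univariate thresholds) is done in R; here we maximise the
// bivariate-normal contingency likelihood over rho with thresholds fixed,
// compute the asymptotic sampling variance from the Fisher information of
// rho, and expose per-observation influence values used to assemble the
// asymptotic covariance of the whole polychoric vector.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "bvn.h"

using namespace Rcpp;

// thresholds padded with -Inf / +Inf; tab is a (possibly weighted) K1 x K2
// contingency table of counts.
static double pc_loglik(const NumericMatrix& tab,
                        const std::vector<double>& a,
                        const std::vector<double>& b,
                        double rho) {
  double ll = 0.0;
  int K1 = tab.nrow(), K2 = tab.ncol();
  for (int i = 0; i < K1; ++i) {
    for (int j = 0; j < K2; ++j) {
      double n_ij = tab(i, j);
      if (n_ij > 0.0) {
        double p = bvn_rect_prob(a[i], a[i + 1], b[j], b[j + 1], rho);
        ll += n_ij * log(p);
      }
    }
  }
  return ll;
}

static std::vector<double> pad_tau(const NumericVector& tau) {
  std::vector<double> out;
  out.reserve(tau.size() + 2);
  out.push_back(R_NegInf);
  for (R_xlen_t i = 0; i < tau.size(); ++i) out.push_back(tau[i]);
  out.push_back(R_PosInf);
  return out;
}

// Brent's method for a bounded scalar maximum (golden section + successive
// parabolic interpolation, as in optimize()).
static double brent_max(const NumericMatrix& tab,
                        const std::vector<double>& a,
                        const std::vector<double>& b,
                        double lo, double hi, double tol, int* iter_out) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv, d = 0.0, e = 0.0;
  x = w = v = lo + gold * (hi - lo);
  fx = fw = fv = pc_loglik(tab, a, b, x);
  int iter = 0;
  for (; iter < 200; ++iter) {
    double xm = 0.5 * (lo + hi);
    double tol1 = tol * fabs(x) + 1e-12;
    double tol2 = 2.0 * tol1;
    if (fabs(x - xm) <= tol2 - 0.5 * (hi - lo)) break;
    bool parabolic = false;
    if (fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = fabs(q);
      double etemp = e;
      e = d;
      if (!(fabs(p) >= fabs(0.5 * q * etemp) || p <= q * (lo - x) ||
            p >= q * (hi - x))) {
        parabolic = true;
        d = p / q;
        double u = x + d;
        if (u - lo < tol2 || hi - u < tol2) d = (xm >= x) ? tol1 : -tol1;
      }
    }
    if (!parabolic) {
      e = (x >= xm) ? lo - x : hi - x;
      d = gold * e;
    }
    double u = (fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = pc_loglik(tab, a, b, u);
    if (fu >= fx) {
      if (u >= x) lo = x; else hi = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) lo = u; else hi = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  if (iter_out) *iter_out = iter;
  return x;
}

// Fisher information for rho per observation: sum over cells (dP/drho)^2 / P
// (second-derivative terms cancel because cell probabilities sum to 1).
static double pc_fisher(const std::vector<double>& a,
                        const std::vector<double>& b,
                        double rho) {
  double info = 0.0;
  int K1 = (int)a.size() - 1, K2 = (int)b.size() - 1;
  for (int i = 0; i < K1; ++i) {
    for (int j = 0; j < K2; ++j) {
      double p = bvn_rect_prob(a[i], a[i + 1], b[j], b[j + 1], rho);
      double dp = bvn_rect_dprob(a[i], a[i + 1], b[j], b[j + 1], rho);
      info += dp * dp / p;
    }
  }
  return info;
}

// [[Rcpp::export(name = ".pc_pair_loglik")]]
double pc_pair_loglik(NumericMatrix tab, NumericVector tau1,
                      NumericVector tau2, double rho) {
  std::vector<double> a = pad_tau(tau1), b = pad_tau(tau2);
  return pc_loglik(tab, a, b, rho);
}

// Two-stage influence algebra for one pair. Thresholds are estimated from
// the univariate margins in stage 1, so the stage-2 correlation inherits
// their sampling error: the per-cell influence is
//   u(a,b) = (s_rho(a,b) - T1(a) - T2(b)) / I_rho,
// where s_rho is the rho-score, T1/T2 propagate the threshold influences
// through the cross-information I_{rho,tau}, and I_rho is the Fisher
// information for rho. Returns the per-cell influence matrix and writes
// the two-stage asymptotic variance (per unit weight) to *avar_out.
static NumericMatrix pc_cell_influence(const NumericMatrix& tab,
                                       const std::vector<double>& a,
                                       const std::vector<double>& b,
                                       double rho, double* avar_out) {
  int K1 = (int)a.size() - 1, K2 = (int)b.size() - 1;
  double n_s = 0.0;
  std::vector<double> rowm(K1, 0.0), colm(K2, 0.0);
  for (int i = 0; i < K1; ++i)
    for (int j = 0; j < K2; ++j) {
      n_s += tab(i, j);
      rowm[i] += tab(i, j);
      colm[j] += tab(i, j);
    }
  NumericMatrix P(K1, K2), S(K1, K2);
  double info = 0.0;
  for (int i = 0; i < K1; ++i)
    for (int j = 0; j < K2; ++j) {
      P(i, j) = bvn_rect_prob(a[i], a[i + 1], b[j], b[j + 1], rho);
      double dp = bvn_rect_dprob(a[i], a[i + 1], b[j], b[j + 1], rho);
      S(i, j) = dp / P(i, j);
      info += dp * S(i, j);
    }
  double s = sqrt(1.0 - rho * rho);
  // cross-information with the K1-1 row thresholds and K2-1 col thresholds
  std::vector<double> c1(K1 - 1, 0.0), c2(K2 - 1, 0.0);
  for (int k = 1; k < K1; ++k) {       // threshold a[k]
    double ph = R::dnorm(a[k], 0, 1, 0);
    for (int j = 0; j < K2; ++j) {
      double up = (b[j + 1] == R_PosInf) ? 1.0
        : R::pnorm((b[j + 1] - rho * a[k]) / s, 0, 1, 1, 0);
      double lo = (b[j] == R_NegInf) ? 0.0
        : R::pnorm((b[j] - rho * a[k]) / s, 0, 1, 1, 0);
      double dPk = ph * (up - lo);     // dP(k-1,j)/da_k = +, dP(k,j)/da_k = -
      c1[k - 1] += dPk * (S(k - 1, j) - S(k, j));
    }
  }
  for (int k = 1; k < K2; ++k) {
    double ph = R::dnorm(b[k], 0, 1, 0);
    for (int i = 0; i < K1; ++i) {
      double up = (a[i + 1] == R_PosInf) ? 1.0
        : R::pnorm((a[i + 1] - rho * b[k]) / s, 0, 1, 1, 0);
      double lo = (a[i] == R_NegInf) ? 0.0
        : R::pnorm((a[i] - rho * b[k]) / s, 0, 1, 1, 0);
      double dPk = ph * (up - lo);
      c2[k - 1] += dPk * (S(i, k - 1) - S(i, k));
    }
  }
  // threshold influences from the margins: psi_k(cat) =
  // (1{cat <= k-1} - F_k) / phi(tau_k); aggregate into per-category terms
  std::vector<double> T1(K1, 0.0), T2(K2, 0.0);
  double F = 0.0;
  for (int k = 1; k < K1; ++k) {
    F += rowm[k - 1] / n_s;
    double ph = R::dnorm(a[k], 0, 1, 0);
    for (int cat = 0; cat < K1; ++cat)
      T1[cat] += c1[k - 1] * (((cat <= k - 1) ? 1.0 : 0.0) - F) / ph;
  }
  F = 0.0;
  for (int k = 1; k < K2; ++k) {
    F += colm[k - 1] / n_s;
    double ph = R::dnorm(b[k], 0, 1, 0);
    for (int cat = 0; cat < K2; ++cat)
      T2[cat] += c2[k - 1] * (((cat <= k - 1) ? 1.0 : 0.0) - F) / ph;
  }
  NumericMatrix U(K1, K2);
  double sum_u2 = 0.0;
  for (int i = 0; i < K1; ++i)
    for (int j = 0; j < K2; ++j) {
      U(i, j) = (info > 0.0) ? (S(i, j) - T1[i] - T2[j]) / info : 0.0;
      sum_u2 += tab(i, j) * U(i, j) * U(i, j);
    }
  if (avar_out)
    *avar_out = (n_s > 0.0) ? sum_u2 / (n_s * n_s) : NA_REAL;
  return U;
}

// [[Rcpp::export(name = ".pc_fit_pair")]]
List pc_fit_pair(NumericMatrix tab, NumericVector tau1, NumericVector tau2,
                 double bound, double tol) {
  std::vector<double> a = pad_tau(tau1), b = pad_tau(tau2);
  int iter = 0;
  double rho = brent_max(tab, a, b, -bound, bound, tol, &iter);
  double n_eff = 0.0;
  for (int i = 0; i < tab.nrow(); ++i)
    for (int j = 0; j < tab.ncol(); ++j) n_eff += tab(i, j);
  double avar = NA_REAL;
  pc_cell_influence(tab, a, b, rho, &avar);
  return List::create(_["rho"] = rho, _["avar"] = avar,
                      _["loglik"] = pc_loglik(tab, a, b, rho),
                      _["n"] = n_eff, _["iterations"] = iter);
}

// Full lower-triangle polychoric matrix with pairwise-present (optionally
// weighted) contingency tables.  y: n x J integer codes 0..K-1, NA = -1.
// Returns rho / avar vectors in column-major lower-triangle order plus, if
// requested, the n x npairs influence matrix for the asymptotic covariance
// of the correlation vector.
// [[Rcpp::export(name = ".pc_matrix_cpp")]]
List pc_matrix_cpp(IntegerMatrix y, List taus, NumericVector w,
                   bool influence, double bound, double tol) {
  int n = y.nrow(), J = y.ncol();
  int npairs = J * (J - 1) / 2;
  NumericVector rho(npairs), avar(npairs), neff(npairs);
  NumericMatrix psi;
  if (influence) psi = NumericMatrix(n, npairs);
  std::vector<std::vector<double> > pad(J);
  std::vector<int> K(J);
  for (int j = 0; j < J; ++j) {
    NumericVector tj = taus[j];
    pad[j] = pad_tau(tj);
    K[j] = tj.size() + 1;
  }
  double wtot = 0.0;
  for (int i = 0; i < n; ++i) wtot += w[i];
  int s = 0;
  for (int j = 0; j < J; ++j) {
    for (int i2 = j + 1; i2 < J; ++i2, ++s) {
      NumericMatrix tab(K[j], K[i2]);
      double n_s = 0.0;
      for (int r = 0; r < n; ++r) {
        int cj = y(r, j), ci = y(r, i2);
        if (cj >= 0 && ci >= 0) {
          tab(cj, ci) += w[r];
          n_s += w[r];
        }
      }
      int iter = 0;
      double rh = brent_max(tab, pad[j], pad[i2], -bound, bound, tol, &iter);
      rho[s] = rh;
      neff[s] = n_s;
      double av = NA_REAL;
      NumericMatrix inf_cell = pc_cell_influence(tab, pad[j], pad[i2], rh,
                                                 &av);
      avar[s] = av;
      if (influence && n_s > 0.0) {
        // rescale by wtot/n_s so crossprod(psi)/wtot^2 estimates
        // cov(rho_s, rho_t)
        double scale = wtot / n_s;
        for (int r = 0; r < n; ++r) {
          int cj = y(r, j), ci = y(r, i2);
          psi(r, s) = (cj >= 0 && ci >= 0)
            ? scale * w[r] * inf_cell(cj, ci) : 0.0;
        }
      }
    }
  }
  List out = List::create(_["rho"] = rho, _["avar"] = avar, _["n"] = neff);
  if (influence) out["influence"] = psi;
  return out;
}
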
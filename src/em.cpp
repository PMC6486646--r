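#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-component EM for residuals r_j with fixed per-SNP null variance v_j and
// a shared free-component variance sigma^2 constrained to sigma^2 >= floor.
// Mixture: pi0 * N(0, v_j) + (1 - pi0) * N(0, sigma^2).
// Densities are handled in log space so that residuals far in the tails of a
// small-variance null component do not underflow the mixture density.

static inline double ldnorm0(double r, double v) {
  return -0.5 * (std::log(2.0 * M_PI * v) + r * r / v);
}

struct EmResult {
  double pi0;
  double s2;
  double ll;
  int iter;
  bool conv;
};

static double loglik_at(const std::vector<double> &r,
                        const std::vector<double> &lf0, double pi0, double s2) {
  const int n = (int)r.size();
  double ll = 0.0;
  if (pi0 >= 1.0) {
    for (int j = 0; j < n; ++j) ll += lf0[j];
    return ll;
  }
  const double lc1 = -0.5 * std::log(2.0 * M_PI * s2);
  if (pi0 <= 0.0) {
    for (int j = 0; j < n; ++j) ll += lc1 - 0.5 * r[j] * r[j] / s2;
    return ll;
  }
  const double lpi = std::log(pi0), l1mpi = std::log1p(-pi0);
  for (int j = 0; j < n; ++j) {
    double a = lpi + lf0[j];
    double b = l1mpi + lc1 - 0.5 * r[j] * r[j] / s2;
    ll += (a > b) ? a + std::log1p(std::exp(b - a))
                  : b + std::log1p(std::exp(a - b));
  }
  return ll;
}

static EmResult em_core(const std::vector<double> &r,
                        const std::vector<double> &lf0, double pi0, double s2,
                        double floor_, double tol, int max_iter,
                        std::vector<double> *trace) {
  const int n = (int)r.size();
  if (s2 < floor_) s2 = floor_;
  if (pi0 < 1e-12) pi0 = 1e-12;
  if (pi0 > 1.0 - 1e-12) pi0 = 1.0 - 1e-12;
  double ll = R_NegInf, ll_prev = R_NegInf;
  double pi_prev = pi0, s2_prev = s2;
  int it = 0;
  bool conv = false;
  for (it = 1; it <= max_iter; ++it) {
    const double lpi = std::log(pi0), l1mpi = std::log1p(-pi0);
    const double lc1 = -0.5 * std::log(2.0 * M_PI * s2);
    double sumg = 0.0, sumw = 0.0, sumwr2 = 0.0;
    ll = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = lpi + lf0[j];
      double b = l1mpi + lc1 - 0.5 * r[j] * r[j] / s2;
      double m = (a > b) ? a + std::log1p(std::exp(b - a))
                         : b + std::log1p(std::exp(a - b));
      ll += m;
      double g = std::exp(a - m);  // null-component responsibility
      sumg += g;
      double w = 1.0 - g;
      sumw += w;
      sumwr2 += w * r[j] * r[j];
    }
    if (trace) trace->push_back(ll);
    if (it > 1 &&
        std::fabs(ll - ll_prev) / (std::fabs(ll_prev) + 1e-300) < tol) {
      // parameters of the previous M-step attain this log-likelihood
      pi0 = pi_prev;
      s2 = s2_prev;
      conv = true;
      break;
    }
    ll_prev = ll;
    pi_prev = pi0;
    s2_prev = s2;
    pi0 = sumg / n;
    if (pi0 < 1e-12) pi0 = 1e-12;
    if (pi0 > 1.0 - 1e-12) pi0 = 1.0 - 1e-12;
    if (sumw > 1e-12) s2 = sumwr2 / sumw;
    if (s2 < floor_) s2 = floor_;
  }
  if (it > max_iter) it = max_iter;
  EmResult out;
  out.pi0 = pi0;
  out.s2 = s2;
  out.ll = ll;
  out.iter = it;
  out.conv = conv;
  return out;
}

// Replace the EM solution by a boundary solution (pure-null pi0 = 1, or
// pure-free pi0 = 0 with sigma^2 at its own constrained optimum) when the
// boundary attains strictly higher likelihood.  EM approaches these
// boundaries only geometrically slowly, e.g. for residuals identically zero.
static EmResult with_boundaries(const std::vector<double> &r,
                                const std::vector<double> &lf0, double floor_,
                                EmResult em) {
  const int n = (int)r.size();
  double ll1 = loglik_at(r, lf0, 1.0, em.s2);
  if (ll1 > em.ll) {
    em.pi0 = 1.0;
    em.ll = ll1;
  }
  double mr2 = 0.0;
  for (int j = 0; j < n; ++j) mr2 += r[j] * r[j];
  mr2 /= n;
  double s2f = (mr2 > floor_) ? mr2 : floor_;
  double ll0 = loglik_at(r, lf0, 0.0, s2f);
  if (ll0 > em.ll) {
    em.pi0 = 0.0;
    em.s2 = s2f;
    em.ll = ll0;
  }
  return em;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector residuals, NumericVector null_vars, double pi0_init,
                double sigma2_init, double eps, double tol, int max_iter,
                bool want_trace) {
  const int n = residuals.size();
  std::vector<double> r(n), lf0(n);
  double vmax = 0.0;
  for (int j = 0; j < n; ++j) {
    r[j] = residuals[j];
    double v = null_vars[j];
    if (!(v > 0)) stop("all null variances must be positive");
    if (v > vmax) vmax = v;
    lf0[j] = ldnorm0(r[j], v);
  }
  const double floor_ = (1.0 + eps) * vmax;
  std::vector<double> trace;
  EmResult em = em_core(r, lf0, pi0_init, sigma2_init, floor_, tol, max_iter,
                        want_trace ? &trace : (std::vector<double> *)0);
  em = with_boundaries(r, lf0, floor_, em);
  List out = List::create(
      _["pi0_hat"] = em.pi0, _["sigma2_hat"] = em.s2, _["loglik"] = em.ll,
      _["n_iter"] = em.iter, _["converged"] = em.conv);
  if (want_trace) out["loglik_trace"] = wrap(trace);
  return out;
}

// Full profile over a grid of candidate causal effects.  At each grid point
// the null variance is v_j = s_y^2 + theta^2 s_x^2 - 2 theta s_xy and the
// residual is r_j = beta_y - theta beta_x.  Each fit is run from a warm start
// (previous grid point's solution) and from the cold default, keeping
// whichever attains the higher likelihood.
// [[Rcpp::export(name = ".pi0_profile_cpp")]]
DataFrame pi0_profile_cpp(NumericVector bx, NumericVector by, NumericVector sx2,
                          NumericVector sy2, double sxy, NumericVector grid,
                          double eps, double tol, int max_iter) {
  const int n = bx.size(), G = grid.size();
  NumericVector pi0(G), s2(G), ll(G), iters(G);
  LogicalVector conv(G);
  std::vector<double> r(n), lf0(n);
  double warm_pi = NA_REAL, warm_s2 = NA_REAL;
  bool have_warm = false;
  for (int g = 0; g < G; ++g) {
    const double th = grid[g];
    double vmax = 0.0, mean_ = 0.0, m2 = 0.0;
    for (int j = 0; j < n; ++j) {
      double v = sy2[j] + th * th * sx2[j] - 2.0 * th * sxy;
      if (!(v > 0))
        stop("non-positive null variance at candidate theta = %f "
             "(invalid overlap covariance)", th);
      if (v > vmax) vmax = v;
      r[j] = by[j] - th * bx[j];
      lf0[j] = ldnorm0(r[j], v);
      mean_ += r[j];
      m2 += r[j] * r[j];
    }
    mean_ /= n;
    const double varr =
        (n > 1) ? (m2 - (double)n * mean_ * mean_) / (n - 1) : 0.0;
    const double floor_ = (1.0 + eps) * vmax;
    double cold_s2 = 2.0 * varr;
    if (cold_s2 < floor_) cold_s2 = floor_;
    EmResult best =
        em_core(r, lf0, 0.5, cold_s2, floor_, tol, max_iter, 0);
    int used = best.iter;
    if (have_warm) {
      EmResult wm =
          em_core(r, lf0, warm_pi, warm_s2, floor_, tol, max_iter, 0);
      used += wm.iter;
      if (wm.ll > best.ll) best = wm;
    }
    best = with_boundaries(r, lf0, floor_, best);
    pi0[g] = best.pi0;
    s2[g] = best.s2;
    ll[g] = best.ll;
    iters[g] = used;
    conv[g] = best.conv;
    warm_pi = best.pi0;
    warm_s2 = best.s2;
    have_warm = true;
  }
  return DataFrame::create(_["theta_tilde"] = grid, _["pi0_hat"] = pi0,
                           _["sigma2_hat"] = s2, _["loglik"] = ll,
                           _["n_iter"] = iters, _["converged"] = conv);
}
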
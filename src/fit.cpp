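// Joint psychometric likelihood kernel and simplex optimizer.
//
// The constrained fit maximizes, over (one PSE per condition, one slope per
// slope-group, one shared lapse, one shared overdispersion scale), the summed
// betabinomial (or binomial) log-likelihood across all (condition, location)
// cells.  The parametric bootstrap refits this model hundreds of thousands of
// times, hence the compiled implementation.  The R-level loglik functions in
// R/likelihood.R are an independent pure-R path used to validate this kernel.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double LAPSE_MAX = 0.1;    // lapse box [0, 0.1]
static const double ETA_LO = 1e-4;      // eta box [1e-4, 0.999]
static const double ETA_HI = 0.999;

static inline double inv_logit(double t) {
  // saturate beyond |t| = 7 so the box boundaries are exactly flat
  // plateaus (otherwise the simplex crawls forever down a vanishing
  // gradient when the optimum sits on a boundary, e.g. eta -> 0);
  // the sacrificed resolution (logistic tail < 1e-3) is likelihood-flat
  if (t > 7.0) t = 7.0;
  if (t < -7.0) t = -7.0;
  if (t > 0) {
    double e = std::exp(-t);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(t);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
double lapse_from_t(double t) { return LAPSE_MAX * inv_logit(t); }

// [[Rcpp::export]]
double eta_from_t(double t) { return ETA_LO + (ETA_HI - ETA_LO) * inv_logit(t); }

// [[Rcpp::export]]
double t_from_lapse(double lapse) {
  double p = std::min(std::max(lapse / LAPSE_MAX, 1e-8), 1.0 - 1e-8);
  return std::log(p / (1.0 - p));
}

// [[Rcpp::export]]
double t_from_eta(double eta) {
  double p = (eta - ETA_LO) / (ETA_HI - ETA_LO);
  p = std::min(std::max(p, 1e-8), 1.0 - 1e-8);
  return std::log(p / (1.0 - p));
}

// Negative joint log-likelihood (combinatorial constants omitted).
// Parameter layout: alpha[0..ncond-1], log beta[0..nslope-1], lapse_t,
// eta_t (betabinomial only).  cond/slope_of_cond are 0-based index maps.
static double nll_joint(const std::vector<double>& par,
                        const NumericVector& xs,
                        const NumericVector& ks,
                        const NumericVector& ns,
                        const IntegerVector& cond,
                        const IntegerVector& slope_of_cond,
                        int ncond, int nslope, bool betabin) {
  const double lapse = LAPSE_MAX * inv_logit(par[ncond + nslope]);
  double etap = 0.0;
  if (betabin) {
    const double eta = ETA_LO + (ETA_HI - ETA_LO) * inv_logit(par[ncond + nslope + 1]);
    etap = 1.0 / (eta * eta) - 1.0;
  }
  double ll = 0.0;
  const int ncell = xs.size();
  // cell term: lg(k+a) + lg(n-k+b) - lg(n+etap) - lg(a) - lg(b) + lg(etap);
  // the etap-only and n-dependent pieces are hoisted/memoized
  const double lg_etap = betabin ? std::lgamma(etap) : 0.0;
  double memo_n = -1.0, memo_lg_n_etap = 0.0;
  for (int i = 0; i < ncell; ++i) {
    const int c = cond[i];
    const double beta = std::exp(par[ncond + slope_of_cond[c]]);
    const double z = beta * (xs[i] - par[c]);
    double psi = lapse + (1.0 - 2.0 * lapse) * 0.5 * std::erfc(-z * M_SQRT1_2);
    // keep strictly interior: lgamma/log diverge at the boundary
    const double eps = 1e-12;
    if (psi < eps) psi = eps;
    if (psi > 1.0 - eps) psi = 1.0 - eps;
    if (betabin) {
      const double a = etap * psi, b = etap * (1.0 - psi);
      if (ns[i] != memo_n) {
        memo_n = ns[i];
        memo_lg_n_etap = std::lgamma(memo_n + etap);
      }
      ll += std::lgamma(ks[i] + a) + std::lgamma(ns[i] - ks[i] + b) -
        memo_lg_n_etap - std::lgamma(a) - std::lgamma(b) + lg_etap;
    } else {
      ll += ks[i] * std::log(psi) + (ns[i] - ks[i]) * std::log1p(-psi);
    }
  }
  if (!std::isfinite(ll)) return 1e30;
  return -ll;
}

// [[Rcpp::export]]
double nll_joint_cpp(NumericVector par, NumericVector xs, NumericVector ks,
                     NumericVector ns, IntegerVector cond,
                     IntegerVector slope_of_cond, int ncond, int nslope,
                     bool betabin) {
  std::vector<double> p(par.begin(), par.end());
  return nll_joint(p, xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);
}

// One Nelder-Mead round from a fresh simplex; helper for nm_fit_cpp.
static void nm_round(std::vector<double>& best_x, double& best_f,
                     const std::vector<double>& step,
                     const NumericVector& xs, const NumericVector& ks,
                     const NumericVector& ns, const IntegerVector& cond,
                     const IntegerVector& slope_of_cond, int ncond, int nslope,
                     bool betabin, int maxit, double tol,
                     int& fevals, bool& converged) {
  const int d = best_x.size();
  std::vector<std::vector<double> > sx(d + 1, best_x);
  std::vector<double> sf(d + 1);
  for (int j = 0; j < d; ++j) sx[j + 1][j] += step[j];
  for (int j = 0; j <= d; ++j)
    sf[j] = nll_joint(sx[j], xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);

  const double rho = 1.0, chi = 2.0, gam = 0.5, sig = 0.5;
  int it = 0, next_check = 400;
  double check_spread = R_PosInf;
  fevals += d + 1;
  converged = false;
  std::vector<double> xc(d), xr(d), xe(d), xk(d);

  while (it++ < maxit) {
    // order
    std::vector<int> idx(d + 1);
    for (int j = 0; j <= d; ++j) idx[j] = j;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return sf[a] < sf[b]; });
    {
      std::vector<std::vector<double> > nx(d + 1);
      std::vector<double> nf(d + 1);
      for (int j = 0; j <= d; ++j) { nx[j] = sx[idx[j]]; nf[j] = sf[idx[j]]; }
      sx.swap(nx); sf.swap(nf);
    }
    // convergence on the function spread; the parameter spread is not
    // required because boundary-flat directions (eta at its box edge)
    // keep the simplex extended without affecting the optimum
    double fspread = sf[d] - sf[0];
    if (fspread < tol) { converged = true; break; }
    // stall detection: healthy simplexes shrink the function spread
    // geometrically; a spread that stops shrinking signals degeneracy,
    // so hand back for a fresh-simplex restart
    if (it >= next_check) {
      if (fspread > 0.5 * check_spread) break;
      check_spread = fspread;
      next_check = it + 400;
    }

    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int v = 0; v < d; ++v) s += sx[v][j];
      xc[j] = s / d;
    }
    for (int j = 0; j < d; ++j) xr[j] = xc[j] + rho * (xc[j] - sx[d][j]);
    double fr = nll_joint(xr, xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);
    ++fevals;
    if (fr < sf[0]) {
      for (int j = 0; j < d; ++j) xe[j] = xc[j] + chi * (xr[j] - xc[j]);
      double fe = nll_joint(xe, xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);
      ++fevals;
      if (fe < fr) { sx[d] = xe; sf[d] = fe; } else { sx[d] = xr; sf[d] = fr; }
    } else if (fr < sf[d - 1]) {
      sx[d] = xr; sf[d] = fr;
    } else {
      bool shrink = false;
      if (fr < sf[d]) { // outside contraction
        for (int j = 0; j < d; ++j) xk[j] = xc[j] + gam * (xr[j] - xc[j]);
        double fk = nll_joint(xk, xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);
        ++fevals;
        if (fk <= fr) { sx[d] = xk; sf[d] = fk; } else shrink = true;
      } else {      // inside contraction
        for (int j = 0; j < d; ++j) xk[j] = xc[j] - gam * (xc[j] - sx[d][j]);
        double fk = nll_joint(xk, xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);
        ++fevals;
        if (fk < sf[d]) { sx[d] = xk; sf[d] = fk; } else shrink = true;
      }
      if (shrink) {
        for (int v = 1; v <= d; ++v) {
          for (int j = 0; j < d; ++j) sx[v][j] = sx[0][j] + sig * (sx[v][j] - sx[0][j]);
          sf[v] = nll_joint(sx[v], xs, ks, ns, cond, slope_of_cond, ncond, nslope, betabin);
          ++fevals;
        }
      }
    }
  }
  int best = 0;
  for (int j = 1; j <= d; ++j) if (sf[j] < sf[best]) best = j;
  best_x = sx[best];
  best_f = sf[best];
}

// Nelder-Mead minimization of nll_joint, with internal fresh-simplex
// restarts: a long run can leave the simplex degenerate (stalled spread
// without convergence); restarting around the incumbent fixes that cheaply.
// [[Rcpp::export]]
List nm_fit_cpp(NumericVector start, NumericVector step, NumericVector xs,
                NumericVector ks, NumericVector ns, IntegerVector cond,
                IntegerVector slope_of_cond, int ncond, int nslope,
                bool betabin, int maxit = 20000, double tol = 1e-8) {
  const int d = start.size();
  std::vector<double> x(start.begin(), start.end());
  std::vector<double> st(step.begin(), step.end());
  double f = 0.0;
  int fevals = 0;
  bool converged = false;
  const int rounds = 4;
  for (int r = 0; r < rounds && !converged; ++r) {
    int budget = (r == 0) ? maxit : maxit / 4;
    nm_round(x, f, st, xs, ks, ns, cond, slope_of_cond, ncond, nslope,
             betabin, budget, tol, fevals, converged);
    for (size_t j = 0; j < st.size(); ++j) st[j] *= 0.25;
  }
  return List::create(_["par"] = NumericVector(x.begin(), x.end()),
                      _["value"] = f, _["fevals"] = fevals,
                      _["converged"] = converged);
}

// Saturated model: one response probability per cell, dispersion fixed.
// Per-cell betabinomial log-likelihood maximized over p by golden-section
// search (the cell likelihood is unimodal in p).
static double saturated_total(const double* ks, const double* ns, int ncell,
                              double eta, double* phat) {
  double total = 0.0;
  const bool betabin = eta > 0.0;
  const double etap = betabin ? (1.0 / (eta * eta) - 1.0) : 0.0;
  const double invphi = (std::sqrt(5.0) - 1.0) / 2.0;
  for (int i = 0; i < ncell; ++i) {
    const double k = ks[i], n = ns[i];
    if (!betabin) {
      double p = k / n;
      phat[i] = p;
      double ll = 0.0;
      if (k > 0) ll += k * std::log(p);
      if (n - k > 0) ll += (n - k) * std::log1p(-p);
      total += ll;
      continue;
    }
    auto cellll = [&](double p) {
      const double a = etap * p, b = etap * (1.0 - p);
      return R::lbeta(k + a, n - k + b) - R::lbeta(a, b);
    };
    double lo = 1e-9, hi = 1.0 - 1e-9;
    double x1 = hi - invphi * (hi - lo), x2 = lo + invphi * (hi - lo);
    double f1 = cellll(x1), f2 = cellll(x2);
    for (int iter = 0; iter < 80 && (hi - lo) > 1e-11; ++iter) {
      if (f1 < f2) {
        lo = x1; x1 = x2; f1 = f2;
        x2 = lo + invphi * (hi - lo); f2 = cellll(x2);
      } else {
        hi = x2; x2 = x1; f2 = f1;
        x1 = hi - invphi * (hi - lo); f1 = cellll(x1);
      }
    }
    const double p = 0.5 * (lo + hi);
    phat[i] = p;
    total += cellll(p);
  }
  return total;
}

// [[Rcpp::export]]
List saturated_fit_cpp(NumericVector ks, NumericVector ns, double eta) {
  NumericVector phat(ks.size());
  double total = saturated_total(ks.begin(), ns.begin(), ks.size(), eta,
                                 phat.begin());
  return List::create(_["loglik"] = total, _["p"] = phat);
}

// Batch warm-started refits for the parametric bootstrap: column b of
// `kmat` holds one replicate's counts; each replicate is refit by
// Nelder-Mead from `start` and its saturated log-likelihood computed at the
// replicate's fitted eta.  Keeping this loop in C++ avoids per-replicate R
// overhead (the calibration tests run 1e5+ refits).
// [[Rcpp::export]]
List boot_refit_cpp(NumericMatrix kmat, NumericVector start,
                    NumericVector step, NumericVector xs, NumericVector ns,
                    IntegerVector cond, IntegerVector slope_of_cond,
                    int ncond, int nslope, bool betabin,
                    int maxit = 20000, double tol = 1e-8) {
  const int n_boot = kmat.ncol();
  const int d = start.size();
  const int ncell = xs.size();
  NumericMatrix par_out(d, n_boot);
  NumericVector loglik(n_boot), sat_loglik(n_boot);
  LogicalVector conv(n_boot);
  std::vector<double> phat(ncell);
  for (int b = 0; b < n_boot; ++b) {
    NumericVector kb = kmat(_, b);
    std::vector<double> x(start.begin(), start.end());
    std::vector<double> st(step.begin(), step.end());
    double f = 0.0;
    int fevals = 0;
    bool converged = false;
    for (int r = 0; r < 4 && !converged; ++r) {
      int budget = (r == 0) ? maxit : maxit / 4;
      nm_round(x, f, st, xs, kb, ns, cond, slope_of_cond, ncond, nslope,
               betabin, budget, tol, fevals, converged);
      for (size_t j = 0; j < st.size(); ++j) st[j] *= 0.25;
    }
    for (int j = 0; j < d; ++j) par_out(j, b) = x[j];
    loglik[b] = -f;
    conv[b] = converged;
    double eta_b = betabin ?
      (ETA_LO + (ETA_HI - ETA_LO) * inv_logit(x[ncond + nslope + 1])) : 0.0;
    sat_loglik[b] = saturated_total(kb.begin(), ns.begin(), ncell, eta_b,
                                    phat.data());
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["par"] = par_out, _["loglik"] = loglik,
                      _["sat_loglik"] = sat_loglik, _["converged"] = conv);
}
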
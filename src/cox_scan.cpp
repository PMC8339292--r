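#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sufficient statistics per distinct event time for a binary covariate:
// d events (d1 in the high group), n at risk (n1 in the high group).
struct TieStats {
  std::vector<double> d, d1, n, n1;
  void clear() { d.clear(); d1.clear(); n.clear(); n1.clear(); }
};

// log partial likelihood, score and information at beta.
// Efron tie correction downweights tied events by j/d; Breslow uses w = 0.
static void cox_derivs(const TieStats &ts, double beta, bool efron,
                       double *ll, double *U, double *I) {
  double eb = std::exp(beta);
  *ll = 0.0; *U = 0.0; *I = 0.0;
  for (size_t k = 0; k < ts.d.size(); ++k) {
    double d = ts.d[k], d1 = ts.d1[k];
    double n1 = ts.n1[k], n0 = ts.n[k] - n1, d0 = d - d1;
    *ll += beta * d1;
    *U += d1;
    int di = (int)d;
    for (int j = 0; j < di; ++j) {
      double w = efron ? (double)j / d : 0.0;
      double A = (n0 + n1 * eb) - w * (d0 + d1 * eb);
      double Be = (n1 - w * d1) * eb;
      *ll -= std::log(A);
      *U -= Be / A;
      *I += Be * (A - Be) / (A * A);
    }
  }
}

// Newton-Raphson with step-halving from beta = 0.
// Fills beta, se, p; estimable = 0 for monotone likelihood / divergence /
// non-convergence. score_test: p from the score statistic at beta = 0
// (log-rank-equivalent); otherwise Wald.
static void cox_fit_core(const TieStats &ts, bool efron, bool score_test,
                         int max_iter, double tol,
                         double *beta_out, double *se_out, double *p_out,
                         int *estimable, int *converged) {
  *beta_out = NA_REAL; *se_out = NA_REAL; *p_out = NA_REAL;
  *estimable = 0; *converged = 0;
  double D = 0.0, D1 = 0.0;
  for (size_t k = 0; k < ts.d.size(); ++k) { D += ts.d[k]; D1 += ts.d1[k]; }
  if (D <= 0.0 || D1 <= 0.0 || D1 >= D) return;  // all events in one group

  double beta = 0.0, ll, U, I;
  cox_derivs(ts, beta, efron, &ll, &U, &I);
  double U0 = U, I0 = I;
  bool conv = false;
  for (int it = 0; it < max_iter; ++it) {
    if (!(I > 0.0)) return;
    double step = U / I;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    double bn = beta + step, lln, Un, In;
    cox_derivs(ts, bn, efron, &lln, &Un, &In);
    int halves = 0;
    while ((!std::isfinite(lln) || lln < ll - 1e-12) && halves < 30) {
      step *= 0.5; bn = beta + step;
      cox_derivs(ts, bn, efron, &lln, &Un, &In);
      ++halves;
    }
    beta = bn; ll = lln; U = Un; I = In;
    if (std::fabs(beta) > 15.0) return;  // monotone likelihood in practice
    if (std::fabs(step) < tol) { conv = true; break; }
  }
  if (!conv || !(I > 0.0)) return;
  *beta_out = beta;
  *se_out = 1.0 / std::sqrt(I);
  if (score_test) {
    double chi2 = (I0 > 0.0) ? U0 * U0 / I0 : 0.0;
    *p_out = R::pchisq(chi2, 1.0, 0, 0);
  } else {
    double z = beta / (*se_out);
    *p_out = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
  }
  if (*p_out <= 0.0) *p_out = std::numeric_limits<double>::min();
  *estimable = 1; *converged = 1;
}

// Build TieStats for one group assignment over data sorted by ascending time.
static void build_stats(const NumericVector &time, const IntegerVector &status,
                        const std::vector<int> &grp, TieStats &ts) {
  int n = time.size();
  ts.clear();
  std::vector<int> suffix1(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) suffix1[i] = suffix1[i + 1] + grp[i];
  int i = 0;
  while (i < n) {
    int j = i;
    double d = 0.0, d1 = 0.0;
    while (j < n && time[j] == time[i]) {
      if (status[j]) { d += 1.0; d1 += grp[j]; }
      ++j;
    }
    if (d > 0.0) {
      ts.d.push_back(d); ts.d1.push_back(d1);
      ts.n.push_back((double)(n - i)); ts.n1.push_back((double)suffix1[i]);
    }
    i = j;
  }
}

static std::vector<int> time_order(const NumericVector &time) {
  std::vector<int> ord(time.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  return ord;
}

// [[Rcpp::export]]
NumericVector cox_fit_cpp(NumericVector time, IntegerVector status,
                          IntegerVector group, bool efron, bool score_test,
                          int max_iter, double tol) {
  int n = time.size();
  std::vector<int> ord = time_order(time);
  NumericVector ts_(n); IntegerVector ss(n); std::vector<int> gs(n);
  for (int i = 0; i < n; ++i) {
    ts_[i] = time[ord[i]]; ss[i] = status[ord[i]]; gs[i] = group[ord[i]];
  }
  TieStats ts;
  build_stats(ts_, ss, gs, ts);
  double beta, se, p; int est, conv;
  cox_fit_core(ts, efron, score_test, max_iter, tol, &beta, &se, &p, &est, &conv);
  return NumericVector::create(
      _["beta"] = beta, _["se"] = se, _["p"] = p,
      _["estimable"] = (double)est, _["converged"] = (double)conv);
}

// Scan one gene: refit the binary Cox model at every candidate cutoff
// (group = expression strictly greater than the cutoff). Returns a matrix
// with one row per cutoff; selection/tie-breaking is done by the caller.
// [[Rcpp::export]]
NumericMatrix cox_scan_cpp(NumericVector expr, NumericVector time,
                           IntegerVector status, NumericVector cutoffs,
                           bool efron, bool score_test, int max_iter,
                           double tol) {
  int n = time.size(), m = cutoffs.size();
  std::vector<int> ord = time_order(time);
  NumericVector ts_(n), es(n); IntegerVector ss(n);
  for (int i = 0; i < n; ++i) {
    ts_[i] = time[ord[i]]; ss[i] = status[ord[i]]; es[i] = expr[ord[i]];
  }
  NumericMatrix out(m, 7);
  colnames(out) = CharacterVector::create("cutoff", "beta", "se", "p",
                                          "n_high", "n_low", "estimable");
  TieStats ts;
  std::vector<int> grp(n);
  for (int c = 0; c < m; ++c) {
    double cut = cutoffs[c];
    int nh = 0;
    for (int i = 0; i < n; ++i) { grp[i] = es[i] > cut ? 1 : 0; nh += grp[i]; }
    out(c, 0) = cut; out(c, 4) = nh; out(c, 5) = n - nh;
    if (nh == 0 || nh == n) {
      out(c, 1) = NA_REAL; out(c, 2) = NA_REAL; out(c, 3) = NA_REAL;
      out(c, 6) = 0.0;
      continue;
    }
    build_stats(ts_, ss, grp, ts);
    double beta, se, p; int est, conv;
    cox_fit_core(ts, efron, score_test, max_iter, tol, &beta, &se, &p, &est, &conv);
    out(c, 1) = beta; out(c, 2) = se; out(c, 3) = p; out(c, 6) = (double)est;
  }
  return out;
}
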
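#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Univariate Cox partial-likelihood machinery for a single *binary* covariate
// with Efron handling of tied event times.  Because the covariate is 0/1 the
// risk-set sums reduce to counts, so one Newton iteration is O(#event-times)
// after an O(n) counting pass per candidate cutoff.  Inputs must be sorted by
// time ascending; ties in time may appear in any order.

struct EventGroup {
  int start;   // first index (in sorted order) of the risk set at this time
  int d0, d1;  // deaths at this time with z = 0 / z = 1
};

// Collect event-time groups once per (time,status) vector.
static std::vector<EventGroup> event_groups(const NumericVector& time,
                                            const IntegerVector& status) {
  int n = time.size();
  std::vector<EventGroup> gs;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && time[j] == time[i]) ++j;
    int d = 0;
    for (int k = i; k < j; ++k) d += status[k];
    if (d > 0) {
      EventGroup g;
      g.start = i;
      g.d0 = 0;
      g.d1 = 0;  // z-split filled per cutoff
      gs.push_back(g);
    }
    i = j;
  }
  return gs;
}

// Efron log-likelihood, score U and information I at beta for the current
// z-assignment (counts per group precomputed in n1r/d0/d1 arrays).
static double efron_eval(double beta, const std::vector<int>& n0r,
                         const std::vector<int>& n1r,
                         const std::vector<int>& d0,
                         const std::vector<int>& d1, double* U, double* I) {
  double eb = std::exp(beta);
  double ll = 0.0, u = 0.0, info = 0.0;
  for (size_t g = 0; g < n0r.size(); ++g) {
    int d = d0[g] + d1[g];
    ll += beta * d1[g];
    u += d1[g];
    for (int k = 0; k < d; ++k) {
      double frac = (double)k / d;
      double A = n0r[g] - frac * d0[g];
      double B = n1r[g] - frac * d1[g];
      double den = A + B * eb;
      double mu = B * eb / den;
      ll -= std::log(den);
      u -= mu;
      info += mu * (1.0 - mu);
    }
  }
  *U = u;
  *I = info;
  return ll;
}

// Newton fit with step-halving.  Returns beta, se, converged flag.
// |beta| is capped at BETA_CAP; hitting the cap marks non-convergence
// (monotone likelihood / complete separation).
static const double BETA_CAP = 22.0;

static void fit_binary(const std::vector<int>& n0r, const std::vector<int>& n1r,
                       const std::vector<int>& d0, const std::vector<int>& d1,
                       double* beta_out, double* se_out, int* conv_out) {
  double beta = 0.0, U, I;
  double ll = efron_eval(beta, n0r, n1r, d0, d1, &U, &I);
  int conv = 0;
  for (int iter = 0; iter < 40; ++iter) {
    if (I <= 0) break;
    double step = U / I;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    double bnew = beta + step;
    double Un, In;
    double lln = efron_eval(bnew, n0r, n1r, d0, d1, &Un, &In);
    int halves = 0;
    while (lln < ll - 1e-12 && halves < 30) {  // enforce ascent
      step /= 2.0;
      bnew = beta + step;
      lln = efron_eval(bnew, n0r, n1r, d0, d1, &Un, &In);
      ++halves;
    }
    beta = bnew;
    U = Un;
    I = In;
    double dll = lln - ll;
    ll = lln;
    if (std::fabs(beta) > BETA_CAP) {
      beta = (beta > 0) ? BETA_CAP : -BETA_CAP;
      efron_eval(beta, n0r, n1r, d0, d1, &U, &I);
      conv = 0;
      break;
    }
    if (std::fabs(U) < 1e-11 * std::max(1.0, I) && std::fabs(dll) < 1e-13) {
      conv = 1;
      break;
    }
  }
  *beta_out = beta;
  *se_out = (I > 0) ? 1.0 / std::sqrt(I) : NA_REAL;
  *conv_out = conv;
}

// Fill per-group z-counts for indicator z and return total (n0, n1).
static void fill_counts(const std::vector<EventGroup>& gs,
                        const IntegerVector& status, const std::vector<int>& z,
                        const NumericVector& time, std::vector<int>& n0r,
                        std::vector<int>& n1r, std::vector<int>& d0,
                        std::vector<int>& d1) {
  int n = z.size();
  // suffix counts of z = 1
  std::vector<int> suf(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) suf[i] = suf[i + 1] + z[i];
  for (size_t g = 0; g < gs.size(); ++g) {
    int a = gs[g].start;
    n1r[g] = suf[a];
    n0r[g] = (n - a) - suf[a];
    int dd0 = 0, dd1 = 0;
    for (int k = a; k < n && time[k] == time[a]; ++k) {
      if (status[k]) {
        if (z[k])
          ++dd1;
        else
          ++dd0;
      }
    }
    d0[g] = dd0;
    d1[g] = dd1;
  }
}

// [[Rcpp::export(name = ".cox_binary_cpp")]]
List cox_binary_cpp(NumericVector time, IntegerVector status,
                    IntegerVector z) {
  int n = time.size();
  std::vector<EventGroup> gs = event_groups(time, status);
  size_t G = gs.size();
  if (G == 0) return List::create(_["beta"] = NA_REAL, _["se"] = NA_REAL,
                                  _["converged"] = 0);
  std::vector<int> n0r(G), n1r(G), d0(G), d1(G), zz(n);
  for (int i = 0; i < n; ++i) zz[i] = z[i];
  fill_counts(gs, status, zz, time, n0r, n1r, d0, d1);
  double beta, se;
  int conv;
  fit_binary(n0r, n1r, d0, d1, &beta, &se, &conv);
  return List::create(_["beta"] = beta, _["se"] = se, _["converged"] = conv);
}

// Scan all candidate cutoffs for one gene.  Returns a matrix with one row per
// cutoff: beta, se, converged, n_above.  z_i = 1 iff x_i > cutoff.
// [[Rcpp::export(name = ".ddg_scan_gene_cpp")]]
NumericMatrix ddg_scan_gene_cpp(NumericVector time, IntegerVector status,
                                NumericVector x, NumericVector cutoffs) {
  int n = time.size(), m = cutoffs.size();
  std::vector<EventGroup> gs = event_groups(time, status);
  size_t G = gs.size();
  NumericMatrix out(m, 6);
  colnames(out) = CharacterVector::create("beta", "se", "converged", "n_above",
                                          "u0", "i0");
  std::vector<int> n0r(G), n1r(G), d0(G), d1(G), z(n);
  for (int c = 0; c < m; ++c) {
    int nab = 0;
    for (int i = 0; i < n; ++i) {
      z[i] = (x[i] > cutoffs[c]) ? 1 : 0;
      nab += z[i];
    }
    if (G == 0 || nab == 0 || nab == n) {
      out(c, 0) = NA_REAL;
      out(c, 1) = NA_REAL;
      out(c, 2) = 0;
      out(c, 3) = nab;
      out(c, 4) = NA_REAL;
      out(c, 5) = NA_REAL;
      continue;
    }
    fill_counts(gs, status, z, time, n0r, n1r, d0, d1);
    double u0, i0;
    efron_eval(0.0, n0r, n1r, d0, d1, &u0, &i0);
    double beta, se;
    int conv;
    fit_binary(n0r, n1r, d0, d1, &beta, &se, &conv);
    out(c, 0) = beta;
    out(c, 1) = se;
    out(c, 2) = conv;
    out(c, 3) = nab;
    out(c, 4) = u0;
    out(c, 5) = i0;
  }
  return out;
}

// Minimum Wald p over the cutoff grid for each column of a permutation-index
// matrix (1-based indices permuting the expression vector against the fixed,
// time-sorted survival data).  Non-converged cutoffs are skipped, matching
// the observed-scan rule.
// [[Rcpp::export(name = ".ddg_minp_perm_cpp")]]
NumericVector ddg_minp_perm_cpp(NumericVector time, IntegerVector status,
                                NumericVector x, NumericVector cutoffs,
                                IntegerMatrix perm) {
  int n = time.size(), P = perm.ncol();
  NumericVector out(P);
  NumericVector xp(n);
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n; ++i) xp[i] = x[perm(i, p) - 1];
    NumericMatrix sc = ddg_scan_gene_cpp(time, status, xp, cutoffs);
    double best = NA_REAL;
    for (int c = 0; c < sc.nrow(); ++c) {
      if (sc(c, 2) != 1) continue;
      double chi = sc(c, 0) / sc(c, 1);
      chi *= chi;
      double pv = R::pchisq(chi, 1.0, 0, 0);
      if (!R_finite(pv)) continue;
      if (!R_finite(best) || pv < best) best = pv;
    }
    out[p] = best;
  }
  return out;
}
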
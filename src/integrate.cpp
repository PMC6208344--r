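#include <Rcpp.h>
using namespace Rcpp;

// Units: V mV, t ms, C nF, g uS, I nA.  Rates are Mainen-style trap
// functions; tadj is the Q10 temperature factor applied to all rate
// constants.

static inline double trap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y + x / 2.0;
  return x / (1.0 - std::exp(-x / y));
}

struct NaKin {
  double vs_act, vs_inact;
  void rates(double v, double tadj,
             double &minf, double &mtau, double &hinf, double &htau) const {
    double va = v - vs_act;
    double am = 0.182 * trap(va + 35.0, 9.0);
    double bm = 0.124 * trap(-(va + 35.0), 9.0);
    mtau = 1.0 / ((am + bm) * tadj);
    minf = am / (am + bm);
    double vi = v - vs_inact;
    double ah = 0.024 * trap(vi + 50.0, 5.0);
    double bh = 0.0091 * trap(-(vi + 75.0), 5.0);
    htau = 1.0 / ((ah + bh) * tadj);
    hinf = 1.0 / (1.0 + std::exp((vi + 65.0) / 6.2));
  }
};

static inline void kdr_rates(double v, double tadj, double &ninf, double &ntau) {
  double a = 0.020 * trap(v - 25.0, 9.0);
  double b = 0.002 * trap(-(v - 25.0), 9.0);
  ntau = 1.0 / ((a + b) * tadj);
  ninf = a / (a + b);
}

static inline void km_rates(double v, double tadj, double &ninf, double &ntau) {
  double a = 0.001 * trap(v + 30.0, 9.0);
  double b = 0.001 * trap(-(v + 30.0), 9.0);
  ntau = 1.0 / ((a + b) * tadj);
  ninf = a / (a + b);
}

// [[Rcpp::export]]
List cable_init_gating(NumericVector v, List kin, double tadj) {
  int n = v.size();
  NaKin na12{as<double>(kin["vs_act12"]), as<double>(kin["vs_inact12"])};
  NaKin na16{as<double>(kin["vs_act16"]), as<double>(kin["vs_inact16"])};
  NumericVector m12(n), h12(n), m16(n), h16(n), nk(n), nm(n);
  for (int i = 0; i < n; ++i) {
    double mi, mt, hi, ht, ni, nt;
    na12.rates(v[i], tadj, mi, mt, hi, ht);
    m12[i] = mi; h12[i] = hi;
    na16.rates(v[i], tadj, mi, mt, hi, ht);
    m16[i] = mi; h16[i] = hi;
    kdr_rates(v[i], tadj, ni, nt); nk[i] = ni;
    km_rates(v[i], tadj, ni, nt);  nm[i] = ni;
  }
  return List::create(_["v"] = clone(v), _["m12"] = m12, _["h12"] = h12,
                      _["m16"] = m16, _["h16"] = h16,
                      _["nkdr"] = nk, _["nkv7"] = nm);
}

// Backward-Euler step on the linear chain: gating advanced by exact
// exponential update at V_t, then the voltage system solved implicitly
// (Thomas algorithm) with channel conductances held at the new gating.
// [[Rcpp::export]]
List cable_run(List state, List pars, double dt, int n_steps,
               double stim_nA, int stim_idx, int on_step, int off_step,
               IntegerVector record_idx) {
  NumericVector v = clone(as<NumericVector>(state["v"]));
  NumericVector m12 = clone(as<NumericVector>(state["m12"]));
  NumericVector h12 = clone(as<NumericVector>(state["h12"]));
  NumericVector m16 = clone(as<NumericVector>(state["m16"]));
  NumericVector h16 = clone(as<NumericVector>(state["h16"]));
  NumericVector nk = clone(as<NumericVector>(state["nkdr"]));
  NumericVector nm = clone(as<NumericVector>(state["nkv7"]));

  NumericVector C = pars["C"], gL = pars["gL"], eL = pars["eL"];
  NumericVector g12 = pars["gna12"], g16 = pars["gna16"];
  NumericVector gkd = pars["gkdr"], gk7 = pars["gkv7"];
  NumericVector ga = pars["ga"];           // length n-1
  double ena = pars["ena"], ek = pars["ek"], tadj = pars["tadj"];
  List kin = pars["kinetics"];
  NaKin na12{as<double>(kin["vs_act12"]), as<double>(kin["vs_inact12"])};
  NaKin na16{as<double>(kin["vs_act16"]), as<double>(kin["vs_inact16"])};

  const int n = v.size();
  const int nrec = record_idx.size();
  NumericMatrix rec(n_steps + 1, nrec);
  for (int k = 0; k < nrec; ++k) rec(0, k) = v[record_idx[k]];

  std::vector<double> diag(n), rhs(n), cp(n), dp(n);

  for (int s = 1; s <= n_steps; ++s) {
    // gating update at V_t
    for (int i = 0; i < n; ++i) {
      double mi, mt, hi, ht, ni, nt;
      if (g12[i] > 0.0) {
        na12.rates(v[i], tadj, mi, mt, hi, ht);
        m12[i] += (mi - m12[i]) * (1.0 - std::exp(-dt / mt));
        h12[i] += (hi - h12[i]) * (1.0 - std::exp(-dt / ht));
      }
      if (g16[i] > 0.0) {
        na16.rates(v[i], tadj, mi, mt, hi, ht);
        m16[i] += (mi - m16[i]) * (1.0 - std::exp(-dt / mt));
        h16[i] += (hi - h16[i]) * (1.0 - std::exp(-dt / ht));
      }
      if (gkd[i] > 0.0) {
        kdr_rates(v[i], tadj, ni, nt);
        nk[i] += (ni - nk[i]) * (1.0 - std::exp(-dt / nt));
      }
      if (gk7[i] > 0.0) {
        km_rates(v[i], tadj, ni, nt);
        nm[i] += (ni - nm[i]) * (1.0 - std::exp(-dt / nt));
      }
    }
    // assemble tridiagonal system
    bool stim_on = (s > on_step && s <= off_step);
    for (int i = 0; i < n; ++i) {
      double gna = g12[i] * m12[i] * m12[i] * m12[i] * h12[i]
                 + g16[i] * m16[i] * m16[i] * m16[i] * h16[i];
      double gk = gkd[i] * nk[i] + gk7[i] * nm[i];
      double gtot = gL[i] + gna + gk;
      double isrc = gL[i] * eL[i] + gna * ena + gk * ek;
      diag[i] = C[i] / dt + gtot;
      rhs[i] = C[i] / dt * v[i] + isrc;
      if (i > 0)      diag[i] += ga[i - 1];
      if (i < n - 1)  diag[i] += ga[i];
      if (stim_on && i == stim_idx) rhs[i] += stim_nA;
    }
    // Thomas solve: off-diagonals are -ga
    cp[0] = -ga[0] / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double m = diag[i] + ga[i - 1] * cp[i - 1];
      cp[i] = (i < n - 1) ? (-ga[i] / m) : 0.0;
      dp[i] = (rhs[i] + ga[i - 1] * dp[i - 1]) / m;
    }
    v[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) v[i] = dp[i] - cp[i] * v[i + 1];

    for (int k = 0; k < nrec; ++k) rec(s, k) = v[record_idx[k]];
    if (!std::isfinite(v[stim_idx]))
      stop("non-finite membrane potential at step %d", s);
  }

  List out_state = List::create(_["v"] = v, _["m12"] = m12, _["h12"] = h12,
                                _["m16"] = m16, _["h16"] = h16,
                                _["nkdr"] = nk, _["nkv7"] = nm);
  return List::create(_["trace"] = rec, _["state"] = out_state);
}
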
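// Conductance-based thalamocortical network engine.
//
// Layers: PY (two-compartment), IN (two-compartment), TC, RE (single
// compartment), Hodgkin-Huxley kinetics.  The axosomatic compartment of
// cortical cells is treated as quasi-stationary (algebraic balance between
// its intrinsic currents and the dendro-somatic coupling).  Membrane
// voltages advance by exponential Euler (exact for piecewise-constant
// conductances); gating variables by the exact exponential relaxation
// update; receptor open fractions are event-driven with per-target
// aggregation (all open fractions of one receptor type decay at the same
// rate beta, so the depression-weighted sum can be decayed with a single
// multiply per target per step).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
#include <random>
#include <cstdint>
#include <string>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double QT = 2.9529;

// x / (1 - exp(-x/k)), with removable singularity (limit k) at x = 0.
static inline double lin_exp(double x, double k) {
  double r = x / k;
  if (std::fabs(r) < 1e-6) return k * (1.0 + 0.5 * r);
  return x / (1.0 - std::exp(-r));
}

struct RR { double xinf, tau; };

// ---------------------------------------------------------------- kinetics
// Cortical fast Na (Mainen-style, as printed; QT on both gates)
static RR py_na_m(double V) {
  double a = 0.182 * lin_exp(V + 25.0, 9.0);
  double b = 0.124 * lin_exp(-(V + 25.0), 9.0);
  return { a / (a + b), 1.0 / (a + b) / QT };
}
static RR py_na_h(double V) {
  double a = 0.024 * lin_exp(V + 40.0, 5.0);
  double b = 0.0091 * lin_exp(-(V + 85.0), 5.0); // pole at -85 mV
  double hinf = 1.0 / (1.0 + std::exp((V + 55.0) / 6.2));
  return { hinf, 1.0 / (a + b) / QT };
}
// Cortical delayed rectifier (single gate, power 1)
static RR py_k_n(double V) {
  double a = 0.02 * lin_exp(V - 25.0, 9.0);
  double b = 0.002 * lin_exp(-(V - 25.0), 9.0);
  return { a / (a + b), 1.0 / (a + b) / QT };
}
// Slow non-inactivating K (Km)
static RR py_km_m(double V) {
  double a = 0.001 * lin_exp(V + 30.0, 9.0);
  double b = 0.001 * lin_exp(-(V + 30.0), 9.0);
  return { a / (a + b), 1.0 / (a + b) / QT };
}
// High-threshold Ca
static RR py_hva_m(double V) {
  double a = 0.055 * lin_exp(V + 27.0, 3.8);
  double b = 0.94 * std::exp((-75.0 - V) / 17.0);
  return { a / (a + b), 1.0 / (a + b) / QT };
}
static RR py_hva_h(double V) {
  double a = 0.000457 * std::exp((-13.0 - V) / 50.0);
  double b = 0.0065 / (std::exp((-V - 15.0) / 28.0) + 1.0);
  return { a / (a + b), 1.0 / (a + b) / QT };
}
// Persistent Na: instantaneous activation.  The open-probability cap is
// 0.02 (model-lineage value); a cap of 0.2 with the tabulated conductances
// makes the resting state linearly unstable (the Down state disappears).
static inline double py_nap_sig(double V) {
  return 1.0 / (1.0 + std::exp(-(V + 42.0) / 5.0));
}
static inline double py_nap_minf(double V) {
  return 0.02 * py_nap_sig(V);
}
// Ca-dependent K (rates from [Ca], not V)
static RR py_kca_m(double ca) {
  double a = 0.01 * ca, b = 0.02;
  return { a / (a + b), 1.0 / (a + b) / QT };
}
// Thalamic fast Na (Traub rates, voltage shift vtr; default -50 mV)
static RR tc_na_m(double V, double vtr) {
  double v = V - vtr;
  double a = 0.32 * lin_exp(v - 13.0, 4.0);
  double b = 0.28 * lin_exp(40.0 - v, 5.0);
  return { a / (a + b), 1.0 / (a + b) };
}
static RR tc_na_h(double V, double vtr) {
  double v = V - vtr;
  double a = 0.128 * std::exp((17.0 - v) / 18.0);
  double b = 4.0 / (1.0 + std::exp((40.0 - v) / 5.0));
  return { a / (a + b), 1.0 / (a + b) };
}
// Thalamic fast K (as printed; single gate, power 4)
static RR tc_k_n(double V) {
  double a = 0.032 * lin_exp(V + 35.0, 5.0);
  double b = 0.5 * std::exp((-40.0 - V) / 40.0);
  return { a / (a + b), 1.0 / (a + b) };
}
// Relay-cell low-threshold Ca (canonical lineage kinetics; smooth taus)
static RR tc_t_m(double V) {
  double minf = 1.0 / (1.0 + std::exp(-(V + 59.0) / 6.2));
  double tau = (0.612 + 1.0 / (std::exp(-(V + 131.6) / 16.7) +
                               std::exp((V + 16.8) / 18.2))) / 3.7372;
  return { minf, tau };
}
static RR tc_t_h(double V) {
  double hinf = 1.0 / (1.0 + std::exp((V + 83.0) / 4.0));
  double tau = (30.8 + (211.4 + std::exp((V + 115.2) / 5.0)) /
                       (1.0 + std::exp((V + 86.0) / 3.2))) / 3.7372;
  return { hinf, tau };
}
// Reticular low-threshold Ca (as printed, incl. fixed tau divisors)
static RR re_t_m(double V) {
  double minf = 1.0 / (1.0 + std::exp(-(V + 52.0) / 7.4));
  double tau = (3.0 + 1.0 / (std::exp((V + 27.0) / 10.0) +
                             std::exp(-(V + 102.0) / 15.0))) / 6.8986;
  return { minf, tau };
}
static RR re_t_h(double V) {
  double hinf = 1.0 / (1.0 + std::exp((V + 80.0) / 5.0));
  double tau = (85.0 + 1.0 / (std::exp((V + 48.0) / 4.0) +
                              std::exp(-(V + 407.0) / 50.0))) / 3.7372;
  return { hinf, tau };
}
// I_h voltage branch: activation h_inf and its time constant tau_s
static RR ih_s(double V) {
  double hinf = 1.0 / (1.0 + std::exp((V + 75.0) / 5.5));
  double taus = 20.0 + 1000.0 / (std::exp((V + 71.5) / 14.2) +
                                 std::exp(-(V + 89.0) / 11.6));
  return { hinf, taus };
}
static inline double nmda_f(double V) {
  return 1.0 / (1.0 + std::exp(-(V + 25.0) / 12.5));
}

// Exact kinetics evaluation for the R-level registry.
// Returns c(m_inf, tau_m, h_inf, tau_h); tau -1 encodes "no such gate",
// tau 0 encodes "instantaneous".
// [[Rcpp::export]]
NumericVector cpp_eval_kinetics(std::string id, double V, double ca,
                                double na_vtr) {
  double mi = 1, tm = -1, hi = 1, th = -1;
  RR r;
  if (id == "PY_Na_soma" || id == "PY_Na_dend") {
    r = py_na_m(V); mi = r.xinf; tm = r.tau;
    r = py_na_h(V); hi = r.xinf; th = r.tau;
  } else if (id == "PY_K") {
    r = py_k_n(V); hi = r.xinf; th = r.tau;       // gate sits in the N slot
  } else if (id == "PY_Nap") {
    mi = py_nap_minf(V); tm = 0;
  } else if (id == "PY_Km") {
    r = py_km_m(V); mi = r.xinf; tm = r.tau;
  } else if (id == "PY_KCa") {
    r = py_kca_m(ca); mi = r.xinf; tm = r.tau;
  } else if (id == "PY_HVA") {
    r = py_hva_m(V); mi = r.xinf; tm = r.tau;
    r = py_hva_h(V); hi = r.xinf; th = r.tau;
  } else if (id == "TC_Na" || id == "RE_Na") {
    r = tc_na_m(V, na_vtr); mi = r.xinf; tm = r.tau;
    r = tc_na_h(V, na_vtr); hi = r.xinf; th = r.tau;
  } else if (id == "TC_K" || id == "RE_K") {
    r = tc_k_n(V); hi = r.xinf; th = r.tau;       // N slot, power 4
  } else if (id == "TC_T") {
    r = tc_t_m(V); mi = r.xinf; tm = r.tau;
    r = tc_t_h(V); hi = r.xinf; th = r.tau;
  } else if (id == "RE_T") {
    r = re_t_m(V); mi = r.xinf; tm = r.tau;
    r = re_t_h(V); hi = r.xinf; th = r.tau;
  } else if (id == "TC_h") {
    r = ih_s(V); mi = r.xinf; tm = r.tau;
  } else if (id == "TC_KL" || id == "RE_KL" || id == "PY_KL" || id == "leak") {
    // no gates
  } else {
    stop("unknown channel id '%s'", id.c_str());
  }
  return NumericVector::create(mi, tm, hi, th);
}

// One mass-action step of the calcium-regulated I_h scheme.
// [[Rcpp::export]]
NumericVector cpp_step_ih(double O, double P1, double OL, double V, double ca,
                          double dt, double k1, double k2, double k3,
                          double k4) {
  RR s = ih_s(V);
  double a = s.xinf / s.tau, b = (1.0 - s.xinf) / s.tau;
  double ca2 = ca * ca, k1c = k1 * ca2 * ca2;
  double dO = a * (1.0 - O - OL) - b * O - k3 * O * P1 + k4 * OL;
  double dP1 = k1c * (1.0 - P1) - k2 * P1 - k3 * O * P1 + k4 * OL;
  double dOL = k3 * O * P1 - k4 * OL;
  O += dt * dO; P1 += dt * dP1; OL += dt * dOL;
  if (O < 0) O = 0; if (O > 1) O = 1;
  if (P1 < 0) P1 = 0; if (P1 > 1) P1 = 1;
  if (OL < 0) OL = 0; if (OL > 1) OL = 1;
  return NumericVector::create(O, P1, OL);
}

// ------------------------------------------------------------- rate tables
struct Tab {
  double v0, idv; int n;
  std::vector<double> xinf, stp;   // stp = 1 - exp(-dt/tau)
  template <class F> void build(F f, double dt, double lo = -130.0,
                                double hi = 60.0, double dv = 0.05) {
    v0 = lo; idv = 1.0 / dv; n = (int)std::floor((hi - lo) / dv) + 1;
    xinf.resize(n); stp.resize(n);
    for (int i = 0; i < n; i++) {
      RR r = f(lo + i * dv);
      xinf[i] = r.xinf;
      stp[i] = 1.0 - std::exp(-dt / r.tau);
    }
  }
  inline void upd(double V, double &x) const {
    double u = (V - v0) * idv;
    if (u < 0) u = 0;
    if (u > n - 1.000001) u = n - 1.000001;
    int i = (int)u; double f = u - i;
    double xi = xinf[i] + f * (xinf[i + 1] - xinf[i]);
    double st = stp[i] + f * (stp[i + 1] - stp[i]);
    x += (xi - x) * st;
  }
};
// fused multi-gate table: one voltage-index computation, contiguous rows
// of (x_inf, 1-exp(-dt/tau)) pairs for all gates of a compartment
struct MTab {
  double v0, idv; int n, ng;
  std::vector<double> d;   // row-major, stride 2*ng
  void build(const std::vector<std::function<RR(double)>> &fs, double dt,
             double lo = -130.0, double hi = 60.0, double dv = 0.05) {
    v0 = lo; idv = 1.0 / dv; n = (int)std::floor((hi - lo) / dv) + 1;
    ng = (int)fs.size();
    d.resize((size_t)n * 2 * ng);
    for (int i = 0; i < n; i++)
      for (int g = 0; g < ng; g++) {
        RR r = fs[g](lo + i * dv);
        d[(size_t)i * 2 * ng + 2 * g] = r.xinf;
        d[(size_t)i * 2 * ng + 2 * g + 1] = 1.0 - std::exp(-dt / r.tau);
      }
  }
  // returns pointers to the two bracketing rows and the fraction
  inline void locate(double V, const double *&r0, const double *&r1,
                     double &f) const {
    double u = (V - v0) * idv;
    if (u < 0) u = 0;
    if (u > n - 1.000001) u = n - 1.000001;
    int i = (int)u; f = u - i;
    r0 = &d[(size_t)i * 2 * ng];
    r1 = r0 + 2 * ng;
  }
  static inline void upd(const double *r0, const double *r1, double f,
                         int g, double &x) {
    double xi = r0[2 * g] + f * (r1[2 * g] - r0[2 * g]);
    double st = r0[2 * g + 1] + f * (r1[2 * g + 1] - r0[2 * g + 1]);
    x += (xi - x) * st;
  }
};

// plain value table (for instantaneous functions)
struct VTab {
  double v0, idv; int n;
  std::vector<double> y;
  template <class F> void build(F f, double lo = -130.0, double hi = 60.0,
                                double dv = 0.05) {
    v0 = lo; idv = 1.0 / dv; n = (int)std::floor((hi - lo) / dv) + 1;
    y.resize(n);
    for (int i = 0; i < n; i++) y[i] = f(lo + i * dv);
  }
  inline double at(double V) const {
    double u = (V - v0) * idv;
    if (u < 0) u = 0;
    if (u > n - 1.000001) u = n - 1.000001;
    int i = (int)u; double f = u - i;
    return y[i] + f * (y[i + 1] - y[i]);
  }
};

// --------------------------------------------------------------- helpers
static double getd(const List &l, const char *n) {
  if (!l.containsElementNamed(n)) stop("config: missing parameter '%s'", n);
  return as<double>(l[n]);
}
static int geti(const List &l, const char *n) {
  if (!l.containsElementNamed(n)) stop("config: missing parameter '%s'", n);
  return as<int>(l[n]);
}

// ------------------------------------------------------- cortical cell rig
// Two-compartment cortical cell under current clamp (exact rates, no
// tables).  inj_dend/inj_soma in nA, sampled per step.
// [[Rcpp::export]]
List cpp_sim_cortical(List p, NumericVector inj_dend, NumericVector inj_soma,
                      double dt, double v0) {
  int nstep = inj_dend.size();
  double rho = getd(p, "rho"), aS = getd(p, "area_soma");
  double aD = rho * aS, Cm = getd(p, "Cm");
  double gL = getd(p, "gL"), EL = getd(p, "EL");
  double gkl = getd(p, "g_kl"), EK = getd(p, "EK"), ENA = getd(p, "ENa");
  double ECA = getd(p, "ECa");
  double gna_d = getd(p, "g_na_dend");
  double gnap_d = getd(p, "g_nap_dend") * getd(p, "nap_cap");
  double ghva = getd(p, "g_hva"), gkca = getd(p, "g_kca");
  double gkm = getd(p, "g_km");
  double gna_s = getd(p, "g_na_soma");
  double gnap_s = getd(p, "g_nap_soma") * getd(p, "nap_cap");
  double gk_s = getd(p, "g_k_soma");
  double Gds = getd(p, "g_couple") * 1e-3;  // uS -> mS
  double carest = getd(p, "ca_rest"), catau = getd(p, "ca_tau");
  double cainflux = getd(p, "ca_influx");
  int soma_iter = geti(p, "soma_iter");

  double vd = v0, vs = v0, ca = carest;
  double m = py_na_m(vd).xinf, h = py_na_h(vd).xinf;
  double mkm = py_km_m(vd).xinf, mkca = py_kca_m(ca).xinf;
  double mhva = py_hva_m(vd).xinf, hhva = py_hva_h(vd).xinf;
  double sm = py_na_m(vs).xinf, sh = py_na_h(vs).xinf, sn = py_k_n(vs).xinf;

  NumericVector VD(nstep), VS(nstep);
  for (int k = 0; k < nstep; k++) {
    // soma: quasi-stationary balance, damped fixed-point on V_S
    double gna_se = gna_s * sm * sm * sm * sh;
    double gk_se = gk_s * sn;
    double vsi = vs;
    for (int it = 0; it < soma_iter; it++) {
      double gnap_se = gnap_s * py_nap_sig(vsi);
      double num = Gds * vd + 1e-3 * inj_soma[k] +
                   aS * ((gna_se + gnap_se) * ENA + gk_se * EK);
      double den = Gds + aS * (gna_se + gnap_se + gk_se);
      double vnew = num / den;
      if (std::fabs(vnew - vsi) < 1e-6) { vsi = vnew; break; }
      vsi = vnew;
    }
    double vs_new = vsi;

    // dendrite: exponential Euler
    double gnap_de = gnap_d * py_nap_sig(vd);
    double gna_de = gna_d * m * m * m * h;
    double ghva_e = ghva * mhva * mhva * hhva;
    double G = gL + gkl + gna_de + gnap_de + ghva_e + gkca * mkca + gkm * mkm;
    double GE = gL * EL + gkl * EK + (gna_de + gnap_de) * ENA + ghva_e * ECA +
                (gkca * mkca + gkm * mkm) * EK;
    double gcp = Gds / aD;
    G += gcp; GE += gcp * vs_new;
    double Eeff = (GE + 1e-3 * inj_dend[k] / aD) / G;
    double vd_new = Eeff + (vd - Eeff) * std::exp(-dt * G / Cm);

    double ihva = ghva_e * (vd - ECA);
    ca += dt * (-cainflux * ihva - (ca - carest) / catau);
    if (ca < 0) ca = 0;

    RR r;
    r = py_na_m(vd); m += (r.xinf - m) * (1 - std::exp(-dt / r.tau));
    r = py_na_h(vd); h += (r.xinf - h) * (1 - std::exp(-dt / r.tau));
    r = py_km_m(vd); mkm += (r.xinf - mkm) * (1 - std::exp(-dt / r.tau));
    r = py_kca_m(ca); mkca += (r.xinf - mkca) * (1 - std::exp(-dt / r.tau));
    r = py_hva_m(vd); mhva += (r.xinf - mhva) * (1 - std::exp(-dt / r.tau));
    r = py_hva_h(vd); hhva += (r.xinf - hhva) * (1 - std::exp(-dt / r.tau));
    r = py_na_m(vs_new); sm += (r.xinf - sm) * (1 - std::exp(-dt / r.tau));
    r = py_na_h(vs_new); sh += (r.xinf - sh) * (1 - std::exp(-dt / r.tau));
    r = py_k_n(vs_new); sn += (r.xinf - sn) * (1 - std::exp(-dt / r.tau));

    vd = vd_new; vs = vs_new;
    VD[k] = vd; VS[k] = vs;
  }
  return List::create(_["V_dend"] = VD, _["V_soma"] = VS);
}

// ------------------------------------------------------- thalamic cell rig
// Single-compartment TC or RE cell under current clamp (exact rates).
// inj in uA/cm^2 per step.
// [[Rcpp::export]]
NumericVector cpp_sim_thalamic(std::string type, List p, NumericVector inj,
                               double dt, double v0) {
  bool is_tc = (type == "TC");
  int nstep = inj.size();
  double Cm = getd(p, "Cm"), gL = getd(p, "gL"), EL = getd(p, "EL");
  double gkl = getd(p, "g_kl"), EK = getd(p, "EK"), ENA = getd(p, "ENa");
  double ECA = getd(p, "ECa"), EH = is_tc ? getd(p, "Eh") : 0.0;
  double gna = getd(p, "g_na"), gk = getd(p, "g_k"), gt = getd(p, "g_t");
  double gh = is_tc ? getd(p, "g_h") : 0.0;
  double ginc = is_tc ? getd(p, "gh_ginc") : 2.0;
  double vtr = getd(p, "na_vtr");
  double carest = getd(p, "ca_rest"), catau = getd(p, "ca_tau");
  double cainflux = getd(p, "ca_influx");
  double k1 = is_tc ? getd(p, "ih_k1") : 0, k2 = is_tc ? getd(p, "ih_k2") : 0;
  double k3 = is_tc ? getd(p, "ih_k3") : 0, k4 = is_tc ? getd(p, "ih_k4") : 0;

  double v = v0, ca = carest;
  double m = tc_na_m(v, vtr).xinf, h = tc_na_h(v, vtr).xinf;
  double n = tc_k_n(v).xinf;
  double mt = is_tc ? tc_t_m(v).xinf : re_t_m(v).xinf;
  double ht = is_tc ? tc_t_h(v).xinf : re_t_h(v).xinf;
  double O = is_tc ? ih_s(v).xinf : 0.0, P1 = 0.0, OLk = 0.0;

  NumericVector V(nstep);
  for (int k = 0; k < nstep; k++) {
    double gna_e = gna * m * m * m * h;
    double n2 = n * n, gk_e = gk * n2 * n2;
    double gt_e = gt * mt * mt * ht;
    double gh_e = gh * (O + ginc * OLk);
    double G = gL + gkl + gna_e + gk_e + gt_e + gh_e;
    double GE = gL * EL + (gkl + gk_e) * EK + gna_e * ENA + gt_e * ECA +
                gh_e * EH;
    double Eeff = (GE + inj[k]) / G;
    double vnew = Eeff + (v - Eeff) * std::exp(-dt * G / Cm);

    double it_cur = gt_e * (v - ECA);
    ca += dt * (-cainflux * it_cur - (ca - carest) / catau);
    if (ca < 0) ca = 0;

    RR r;
    r = tc_na_m(v, vtr); m += (r.xinf - m) * (1 - std::exp(-dt / r.tau));
    r = tc_na_h(v, vtr); h += (r.xinf - h) * (1 - std::exp(-dt / r.tau));
    r = tc_k_n(v); n += (r.xinf - n) * (1 - std::exp(-dt / r.tau));
    if (is_tc) {
      r = tc_t_m(v); mt += (r.xinf - mt) * (1 - std::exp(-dt / r.tau));
      r = tc_t_h(v); ht += (r.xinf - ht) * (1 - std::exp(-dt / r.tau));
      NumericVector s = cpp_step_ih(O, P1, OLk, v, ca, dt, k1, k2, k3, k4);
      O = s[0]; P1 = s[1]; OLk = s[2];
    } else {
      r = re_t_m(v); mt += (r.xinf - mt) * (1 - std::exp(-dt / r.tau));
      r = re_t_h(v); ht += (r.xinf - ht) * (1 - std::exp(-dt / r.tau));
    }
    v = vnew;
    V[k] = v;
  }
  return V;
}

// ----------------------------------------------------------- network engine
struct Proj {
  int src_layer, tgt_layer, receptor;   // 0 AMPA, 1 NMDA, 2 GABAA, 3 GABAB
  double g;                             // uS
  bool dep; double U;
  std::vector<int> offs;                // CSR over source cells
  std::vector<int> tgt;
  // receptor state is per SOURCE cell: every connection from one source
  // sees the same spike train, so open fractions (and the GABAB cascade)
  // coincide across its connections.
  std::vector<double> O, tl;            // per source (AMPA/NMDA/GABAA)
  std::vector<double> Rg, Gg;           // per source (GABAB)
  std::vector<double> D, Dlast;         // per source
  std::vector<double> A;                // per target: sum_j D_j O_j
  double beta, step_dec, pulse_inf, pulse_dec;
  double r_pulse_inf, r_pulse_dec;      // GABAB R pulse
};

struct EvLog {
  std::vector<double> t, aux;
  std::vector<int> kind, point;
  void add(double tt, int k, int pt, double ax) {
    t.push_back(tt); kind.push_back(k); point.push_back(pt); aux.push_back(ax);
  }
};

class NetSim {
public:
  // config scalars
  double dt; long nsteps; int rec_stride;
  double tau_rec;
  double E_ampa, E_gabaa, E_gabaa_tc, E_K;
  double gb_K1, gb_K2, gb_K3, gb_K4, gb_Kd;
  // layer sizes
  int nPY, nIN, nTC, nRE;
  // cortical params (per class)
  struct CortP {
    double aS, aD, Cm, gL, EL, gkl, gna_d, gnap_d, ghva, gkca, gkm;
    double gna_s, gnap_s, gk_s, Gds;
    double carest, catau, cainflux;
    int soma_iter;
  } pyP, inP;
  struct ThalP {
    double area, Cm, gL, EL, gkl, gna, gk, gt, gh, ginc, vtr;
    double carest, catau, cainflux, k1, k2, k3, k4;
  } tcP, reP;
  double ENA, EK, ECA, EH;

  // state
  std::vector<double> pyVD, pyVS, pyNaM, pyNaH, pyKmM, pyKcaM, pyHvaM,
      pyHvaH, pyCa, pySM, pySH, pySN_, pyLast;
  std::vector<double> inVD, inVS, inNaM, inNaH, inKmM, inKcaM, inHvaM,
      inHvaH, inCa, inSM, inSH, inSN_, inLast;
  std::vector<double> tcV, tcNaM, tcNaH, tcKN, tcTM, tcTH, tcCa, tcO, tcP1,
      tcOL, tcLast;
  std::vector<double> reV, reNaM, reNaH, reKN, reTM, reTH, reLast;

  // per-cell heterogeneity (drawn once per run from the seed)
  std::vector<double> pyGL, pyGKL, pyGNAP, pyGKCA, pyEL;
  std::vector<double> inGL, inGKL, inGKCA, inEL;
  std::vector<double> tcGL, tcGKL, tcGT, tcGH, tcEL;
  std::vector<double> reGL, reGKL, reGT, reEL;
  double heterog;

  std::vector<Proj> projs;
  std::vector<std::vector<int>> by_src_layer; // proj indices per source layer
  std::vector<std::vector<int>> by_tgt_layer; // proj indices per target layer

  // mini drive
  double mini_rate_py, mini_rate_in, mini_g_py, mini_g_in;
  std::vector<double> miniO_py, miniTl_py, miniNext_py;
  std::vector<double> miniO_in, miniTl_in, miniNext_in;
  bool mini_on;
  // sensory neuron
  double g_sn; std::deque<double> sn_times;
  double snO, snTl;
  // receptor constants (AMPA kinetics for minis/SN)
  double am_beta, am_step_dec, am_pulse_inf, am_pulse_dec;
  double gb_e2, gb_e4, gb_c23;
  std::vector<double> gbcond_tc; // per-TC GABAB conductance this step

  // detector
  double det_silence, det_term, det_rearm; int det_nspk;
  double last_py_spk, silence_from, first_cnt_t;
  bool armed; int cnt;
  // P4 tracker
  double p4_frac, p4_min; int p4_win_ms;
  std::vector<int> p4_bins; int p4_bin_pos; double p4_peak; bool p4_track;
  long next_ms_step;
  // protocol
  int protocol, point; double delay_ms, pause_ms, dst_limit, cue_ms,
      sn_rate;
  double pause_until; int pair_idx; bool dst_resume;
  double last_down_dur;

  // fused tables: cortical dendrite (NaM,NaH,Km,HvaM,HvaH), cortical
  // soma (NaM,NaH,KN), TC (NaM,NaH,KN,TM,TH), RE (NaM,NaH,KN,TM,TH)
  MTab tCD, tCS, tTC, tRE;
  VTab tNap, tNmda, tIhInf, tIhTau;

  // rng
  std::mt19937_64 rng;
  inline double runif() {
    return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rexp(double rate) { return -std::log(runif()) / rate; }

  // output
  std::vector<double> lfp; // -sum of PY postsynaptic currents (nA)
  std::vector<double> spk_t; std::vector<int> spk_layer, spk_idx;
  EvLog ev;
  IntegerVector rec_py, rec_tc, rec_re, rec_in;
  std::vector<std::vector<double>> traces;

  double t;

  void setup(const List &cfg);
  void run();
  void on_spike(int layer, int idx);
  void trigger_protocol(double tt);
  void schedule_cue(double cue_t);
  List result();
};

static void read_cort(const List &p, NetSim::CortP &o) {
  double rho = getd(p, "rho");
  o.aS = getd(p, "area_soma"); o.aD = rho * o.aS;
  o.Cm = getd(p, "Cm"); o.gL = getd(p, "gL"); o.EL = getd(p, "EL");
  o.gkl = getd(p, "g_kl");
  double ncap = getd(p, "nap_cap");
  o.gna_d = getd(p, "g_na_dend"); o.gnap_d = getd(p, "g_nap_dend") * ncap;
  o.ghva = getd(p, "g_hva"); o.gkca = getd(p, "g_kca");
  o.gkm = getd(p, "g_km");
  o.gna_s = getd(p, "g_na_soma"); o.gnap_s = getd(p, "g_nap_soma") * ncap;
  o.gk_s = getd(p, "g_k_soma");
  o.Gds = getd(p, "g_couple") * 1e-3;
  o.carest = getd(p, "ca_rest"); o.catau = getd(p, "ca_tau");
  o.cainflux = getd(p, "ca_influx");
  o.soma_iter = geti(p, "soma_iter");
}
static void read_thal(const List &p, NetSim::ThalP &o, bool is_tc) {
  o.area = getd(p, "area");
  o.Cm = getd(p, "Cm"); o.gL = getd(p, "gL"); o.EL = getd(p, "EL");
  o.gkl = getd(p, "g_kl"); o.gna = getd(p, "g_na"); o.gk = getd(p, "g_k");
  o.gt = getd(p, "g_t"); o.vtr = getd(p, "na_vtr");
  o.carest = getd(p, "ca_rest"); o.catau = getd(p, "ca_tau");
  o.cainflux = getd(p, "ca_influx");
  if (is_tc) {
    o.gh = getd(p, "g_h"); o.ginc = getd(p, "gh_ginc");
    o.k1 = getd(p, "ih_k1"); o.k2 = getd(p, "ih_k2");
    o.k3 = getd(p, "ih_k3"); o.k4 = getd(p, "ih_k4");
  } else { o.gh = 0; o.ginc = 2; o.k1 = o.k2 = o.k3 = o.k4 = 0; }
}

void NetSim::setup(const List &cfg) {
  dt = getd(cfg, "dt");
  nsteps = (long)std::llround(getd(cfg, "duration_ms") / dt);
  rec_stride = std::max(1, (int)std::lround(1.0 / (getd(cfg, "fs_record") *
                                                   1e-3 * dt)));
  rng.seed((uint64_t)getd(cfg, "seed"));

  List rev = cfg["reversal"];
  ENA = getd(rev, "ENa"); EK = getd(rev, "EK"); ECA = getd(rev, "ECa");
  EH = getd(rev, "Eh");
  E_ampa = getd(rev, "E_ampa"); E_gabaa = getd(rev, "E_gabaa");
  E_gabaa_tc = getd(rev, "E_gabaa_tc"); E_K = EK;

  List lay = cfg["layers"];
  nPY = geti(lay, "PY"); nIN = geti(lay, "IN");
  nTC = geti(lay, "TC"); nRE = geti(lay, "RE");

  read_cort(cfg["py"], pyP); read_cort(cfg["in"], inP);
  read_thal(cfg["tc"], tcP, true); read_thal(cfg["re"], reP, false);

  List syn = cfg["syn"];
  tau_rec = getd(syn, "tau_rec");
  double A = getd(syn, "A"), tmax = getd(syn, "t_max");
  double a_am = getd(syn, "alpha_ampa"), b_am = getd(syn, "beta_ampa");
  double a_ga = getd(syn, "alpha_gabaa"), b_ga = getd(syn, "beta_gabaa");
  double a_nm = getd(syn, "alpha_nmda"), b_nm = getd(syn, "beta_nmda");
  gb_K1 = getd(syn, "gabab_K1"); gb_K2 = getd(syn, "gabab_K2");
  gb_K3 = getd(syn, "gabab_K3"); gb_K4 = getd(syn, "gabab_K4");
  gb_Kd = getd(syn, "gabab_Kd");

  auto mk_pulse = [&](double a, double b, double &pinf, double &pdec) {
    double k = a * A + b;
    pinf = a * A / k; pdec = std::exp(-k * tmax);
  };
  am_beta = b_am; am_step_dec = std::exp(-b_am * dt);
  mk_pulse(a_am, b_am, am_pulse_inf, am_pulse_dec);
  double nm_pinf, nm_pdec, ga_pinf, ga_pdec;
  mk_pulse(a_nm, b_nm, nm_pinf, nm_pdec);
  mk_pulse(a_ga, b_ga, ga_pinf, ga_pdec);
  double gbr_k = gb_K1 * A + gb_K2;
  double gbr_pinf = gb_K1 * A / gbr_k, gbr_pdec = std::exp(-gbr_k * tmax);
  gb_e2 = std::exp(-gb_K2 * dt); gb_e4 = std::exp(-gb_K4 * dt);
  gb_c23 = gb_K3 * (gb_e2 - gb_e4) / (gb_K4 - gb_K2);

  // projections
  List plist = cfg["projections"];
  int nlayers = 4;
  by_src_layer.assign(nlayers, {});
  by_tgt_layer.assign(nlayers, {});
  int lsz[4] = { nPY, nIN, nTC, nRE };
  for (int pi = 0; pi < plist.size(); pi++) {
    List pd = plist[pi];
    Proj pr;
    pr.src_layer = geti(pd, "src_layer"); pr.tgt_layer = geti(pd, "tgt_layer");
    pr.receptor = geti(pd, "receptor");
    pr.g = getd(pd, "g");
    pr.dep = geti(pd, "depress") != 0; pr.U = getd(pd, "U");
    IntegerVector src = pd["src"], tgt = pd["tgt"]; // 0-based, sorted by src
    int ns = lsz[pr.src_layer], nt = lsz[pr.tgt_layer], nc = src.size();
    pr.offs.assign(ns + 1, 0);
    for (int c = 0; c < nc; c++) pr.offs[src[c] + 1]++;
    for (int s = 0; s < ns; s++) pr.offs[s + 1] += pr.offs[s];
    pr.tgt.assign(tgt.begin(), tgt.end());
    pr.A.assign(nt, 0.0);
    pr.D.assign(ns, 1.0); pr.Dlast.assign(ns, -1e18);
    (void)nt; (void)nc;
    if (pr.receptor == 3) {
      pr.Rg.assign(ns, 0.0); pr.Gg.assign(ns, 0.0);
      pr.r_pulse_inf = gbr_pinf; pr.r_pulse_dec = gbr_pdec;
    } else {
      pr.O.assign(ns, 0.0); pr.tl.assign(ns, 0.0);
      if (pr.receptor == 0) { pr.beta = b_am; pr.pulse_inf = am_pulse_inf;
        pr.pulse_dec = am_pulse_dec; }
      else if (pr.receptor == 1) { pr.beta = b_nm; pr.pulse_inf = nm_pinf;
        pr.pulse_dec = nm_pdec; }
      else { pr.beta = b_ga; pr.pulse_inf = ga_pinf; pr.pulse_dec = ga_pdec; }
      pr.step_dec = std::exp(-pr.beta * dt);
    }
    by_src_layer[pr.src_layer].push_back((int)projs.size());
    by_tgt_layer[pr.tgt_layer].push_back((int)projs.size());
    projs.push_back(std::move(pr));
  }
  gbcond_tc.assign(nTC, 0.0);

  // mini drive
  List mini = cfg["mini"];
  mini_rate_py = getd(mini, "rate_py"); mini_rate_in = getd(mini, "rate_in");
  mini_g_py = getd(mini, "g_py"); mini_g_in = getd(mini, "g_in");
  miniO_py.assign(nPY, 0); miniTl_py.assign(nPY, 0);
  miniNext_py.assign(nPY, 1e18);
  miniO_in.assign(nIN, 0); miniTl_in.assign(nIN, 0);
  miniNext_in.assign(nIN, 1e18);
  mini_on = false;

  // stimulation
  List st = cfg["stim"];
  protocol = geti(st, "protocol"); point = geti(st, "point");
  delay_ms = getd(st, "delay_ms"); pause_ms = getd(st, "pause_ms");
  dst_limit = getd(st, "dst_limit_ms"); cue_ms = getd(st, "cue_ms");
  sn_rate = getd(st, "sn_rate"); g_sn = getd(st, "g_sn");
  p4_frac = getd(st, "p4_frac"); p4_min = getd(st, "p4_min_rate");
  p4_win_ms = geti(st, "p4_smooth_ms");
  snO = 0; snTl = 0;
  pause_until = -1e18; pair_idx = 0; dst_resume = true; last_down_dur = 1e9;

  List det = cfg["detector"];
  det_silence = getd(det, "silence_ms"); det_nspk = geti(det, "n_spikes");
  det_term = getd(det, "term_silence_ms"); det_rearm = getd(det, "rearm_ms");
  last_py_spk = 0.0; armed = false; cnt = 0; silence_from = 0;
  first_cnt_t = 0;
  p4_bins.assign(p4_win_ms, 0); p4_bin_pos = 0; p4_peak = 0; p4_track = false;
  next_ms_step = 0;

  // state init
  auto initc = [&](int n, CortP &P, std::vector<double> &VD,
                   std::vector<double> &VS, std::vector<double> &NaM,
                   std::vector<double> &NaH, std::vector<double> &KmM,
                   std::vector<double> &KcaM, std::vector<double> &HvaM,
                   std::vector<double> &HvaH, std::vector<double> &Ca,
                   std::vector<double> &SM, std::vector<double> &SH,
                   std::vector<double> &SN, std::vector<double> &Last) {
    double v0 = P.EL;
    VD.assign(n, v0); VS.assign(n, v0);
    NaM.assign(n, py_na_m(v0).xinf); NaH.assign(n, py_na_h(v0).xinf);
    KmM.assign(n, py_km_m(v0).xinf);
    KcaM.assign(n, py_kca_m(P.carest).xinf);
    HvaM.assign(n, py_hva_m(v0).xinf); HvaH.assign(n, py_hva_h(v0).xinf);
    Ca.assign(n, P.carest);
    SM.assign(n, py_na_m(v0).xinf); SH.assign(n, py_na_h(v0).xinf);
    SN.assign(n, py_k_n(v0).xinf);
    Last.assign(n, -1e9);
  };
  initc(nPY, pyP, pyVD, pyVS, pyNaM, pyNaH, pyKmM, pyKcaM, pyHvaM, pyHvaH,
        pyCa, pySM, pySH, pySN_, pyLast);
  initc(nIN, inP, inVD, inVS, inNaM, inNaH, inKmM, inKcaM, inHvaM, inHvaH,
        inCa, inSM, inSH, inSN_, inLast);
  double vt0 = -68.0;
  tcV.assign(nTC, vt0);
  tcNaM.assign(nTC, tc_na_m(vt0, tcP.vtr).xinf);
  tcNaH.assign(nTC, tc_na_h(vt0, tcP.vtr).xinf);
  tcKN.assign(nTC, tc_k_n(vt0).xinf);
  tcTM.assign(nTC, tc_t_m(vt0).xinf); tcTH.assign(nTC, tc_t_h(vt0).xinf);
  tcCa.assign(nTC, tcP.carest);
  tcO.assign(nTC, ih_s(vt0).xinf); tcP1.assign(nTC, 0.0);
  tcOL.assign(nTC, 0.0);
  tcLast.assign(nTC, -1e9);
  double vr0 = -80.0;
  reV.assign(nRE, vr0);
  reNaM.assign(nRE, tc_na_m(vr0, reP.vtr).xinf);
  reNaH.assign(nRE, tc_na_h(vr0, reP.vtr).xinf);
  reKN.assign(nRE, tc_k_n(vr0).xinf);
  reTM.assign(nRE, re_t_m(vr0).xinf); reTH.assign(nRE, re_t_h(vr0).xinf);
  reLast.assign(nRE, -1e9);

  // per-cell heterogeneity: multiplicative jitter on passive/slow
  // conductances, additive jitter on leak reversal
  // per-cell heterogeneity: independent multiplicative jitter on passive
  // and slow conductances, additive jitter on leak reversals, drawn once
  // per run from the seed
  heterog = getd(cfg, "heterogeneity");
  auto jitter = [&](int n, double base, bool additiveE) {
    std::vector<double> v(n);
    for (int i = 0; i < n; i++) {
      double q = 2.0 * runif() - 1.0;
      v[i] = additiveE ? base + 20.0 * heterog * q
                       : base * (1.0 + heterog * q);
    }
    return v;
  };
  pyGL = jitter(nPY, pyP.gL, false); pyGKL = jitter(nPY, pyP.gkl, false);
  pyGNAP = jitter(nPY, pyP.gnap_d, false);
  pyGKCA = jitter(nPY, pyP.gkca, false);
  pyEL = jitter(nPY, pyP.EL, true);
  inGL = jitter(nIN, inP.gL, false); inGKL = jitter(nIN, inP.gkl, false);
  inGKCA = jitter(nIN, inP.gkca, false);
  inEL = jitter(nIN, inP.EL, true);
  tcGL = jitter(nTC, tcP.gL, false); tcGKL = jitter(nTC, tcP.gkl, false);
  tcGT = jitter(nTC, tcP.gt, false); tcGH = jitter(nTC, tcP.gh, false);
  tcEL = jitter(nTC, tcP.EL, true);
  reGL = jitter(nRE, reP.gL, false); reGKL = jitter(nRE, reP.gkl, false);
  reGT = jitter(nRE, reP.gt, false);
  reEL = jitter(nRE, reP.EL, true);

  // tables
  tCD.build({py_na_m, py_na_h, py_km_m, py_hva_m, py_hva_h}, dt);
  tCS.build({py_na_m, py_na_h, py_k_n}, dt);
  double vtr_tc = tcP.vtr, vtr_re = reP.vtr;
  tTC.build({[vtr_tc](double V) { return tc_na_m(V, vtr_tc); },
             [vtr_tc](double V) { return tc_na_h(V, vtr_tc); },
             tc_k_n, tc_t_m, tc_t_h}, dt);
  tRE.build({[vtr_re](double V) { return tc_na_m(V, vtr_re); },
             [vtr_re](double V) { return tc_na_h(V, vtr_re); },
             tc_k_n, re_t_m, re_t_h}, dt);
  tNap.build(py_nap_sig); tNmda.build(nmda_f);
  tIhInf.build([](double V) { return ih_s(V).xinf; });
  tIhTau.build([](double V) { return ih_s(V).tau; });

  // recording
  List rc = cfg["record"];
  rec_py = rc["PY"]; rec_in = rc["IN"]; rec_tc = rc["TC"]; rec_re = rc["RE"];
  int ntr = rec_py.size() + rec_in.size() + rec_tc.size() + rec_re.size();
  traces.assign(ntr, {});
  long nrec = nsteps / rec_stride + 1;
  lfp.reserve(nrec);
  for (auto &tr : traces) tr.reserve(nrec);

  t = 0.0;
  // mini drive starts armed: the run begins in a silent Down state
  mini_on = true;
  for (int i = 0; i < nPY; i++) miniNext_py[i] = rexp(mini_rate_py * 1e-3);
  for (int i = 0; i < nIN; i++) miniNext_in[i] = rexp(mini_rate_in * 1e-3);
}

void NetSim::schedule_cue(double cue_t) {
  int nspk = std::max(1, (int)std::lround(cue_ms * sn_rate * 1e-3));
  double isi = 1000.0 / sn_rate;
  for (int k = 0; k < nspk; k++) sn_times.push_back(cue_t + k * isi);
  ev.add(cue_t, 2 /*CUE*/, point, 0.0);
}

void NetSim::trigger_protocol(double tt) {
  if (protocol == 0) return;
  if (tt < pause_until) return;
  double cue_t = tt + delay_ms;
  if (protocol == 1) {          // CLS: two cues then pause
    schedule_cue(cue_t);
    if (++pair_idx >= 2) {
      pair_idx = 0;
      pause_until = cue_t + pause_ms;
      ev.add(cue_t, 3, point, pause_ms);
      ev.add(pause_until, 4, point, 0.0);
    }
  } else if (protocol == 2) {   // sCLS: pause after every cue
    schedule_cue(cue_t);
    pause_until = cue_t + pause_ms;
    ev.add(cue_t, 3, point, pause_ms);
    ev.add(pause_until, 4, point, 0.0);
  } else if (protocol == 3) {   // DSt
    if (dst_resume || last_down_dur < dst_limit) {
      schedule_cue(cue_t);
      dst_resume = false;
    } else {
      pause_until = tt + pause_ms;
      dst_resume = true;
      ev.add(tt, 3, point, pause_ms);
      ev.add(pause_until, 4, point, 0.0);
    }
  }
}

void NetSim::on_spike(int layer, int idx) {
  spk_t.push_back(t); spk_layer.push_back(layer); spk_idx.push_back(idx);
  // synaptic fan-out
  for (int pi : by_src_layer[layer]) {
    Proj &p = projs[pi];
    int c0 = p.offs[idx], c1 = p.offs[idx + 1];
    if (c0 == c1) continue;
    if (p.receptor == 3) {
      p.Rg[idx] = p.r_pulse_inf + (p.Rg[idx] - p.r_pulse_inf) * p.r_pulse_dec;
      continue;
    }
    double Dprev = p.D[idx], Dnew = 1.0;
    if (p.dep) {
      Dnew = 1.0 - (1.0 - Dprev * (1.0 - p.U)) *
                       std::exp(-(t - p.Dlast[idx]) / tau_rec);
      p.D[idx] = Dnew; p.Dlast[idx] = t;
    }
    double Odec = p.O[idx] * std::exp(-p.beta * (t - p.tl[idx]));
    double Onew = p.pulse_inf + (Odec - p.pulse_inf) * p.pulse_dec;
    double delta = Dnew * Onew - Dprev * Odec;
    p.O[idx] = Onew; p.tl[idx] = t;
    for (int c = c0; c < c1; c++) p.A[p.tgt[c]] += delta;
  }
  if (layer == 0) {             // PY spike: detector bookkeeping
    if (armed) {
      if (cnt == 0) first_cnt_t = t;
      if (++cnt >= det_nspk) {
        double down_dur = first_cnt_t - silence_from;
        ev.add(t, 1 /*SO_DETECT*/, 0, down_dur);
        last_down_dur = down_dur;
        armed = false; cnt = 0;
        mini_on = false;
        for (int i = 0; i < nPY; i++) miniNext_py[i] = 1e18;
        for (int i = 0; i < nIN; i++) miniNext_in[i] = 1e18;
        p4_track = true; p4_peak = 0.0;
        if (point <= 3) trigger_protocol(t);
      }
    }
    last_py_spk = t;
    p4_bins[p4_bin_pos]++;
  }
}

void NetSim::run() {
  const double mini_delay = det_term + det_rearm;
  long ms_stride = (long)std::lround(1.0 / dt);
  long check_stride = 40 * ms_stride;

  for (long step = 0; step < nsteps; step++) {
    t = step * dt;

    // --- events: sensory-neuron spikes and minis --------------------------
    while (!sn_times.empty() && sn_times.front() <= t + 1e-9) {
      sn_times.pop_front();
      snO = am_pulse_inf + (snO - am_pulse_inf) * am_pulse_dec;
    }
    if (mini_on) {
      for (int i = 0; i < nPY; i++)
        if (t >= miniNext_py[i]) {
          miniO_py[i] = am_pulse_inf + (miniO_py[i] - am_pulse_inf) *
                        am_pulse_dec;
          miniNext_py[i] = t + rexp(mini_rate_py * 1e-3);
        }
      for (int i = 0; i < nIN; i++)
        if (t >= miniNext_in[i]) {
          miniO_in[i] = am_pulse_inf + (miniO_in[i] - am_pulse_inf) *
                        am_pulse_dec;
          miniNext_in[i] = t + rexp(mini_rate_in * 1e-3);
        }
    } else if (t - last_py_spk >= mini_delay) {
      mini_on = true;
      for (int i = 0; i < nPY; i++) miniNext_py[i] = t + rexp(mini_rate_py * 1e-3);
      for (int i = 0; i < nIN; i++) miniNext_in[i] = t + rexp(mini_rate_in * 1e-3);
    }

    // --- per-step synapse state -------------------------------------------
    for (auto &p : projs) {
      if (p.receptor == 3) continue;
      for (auto &a : p.A) { a *= p.step_dec; if (a < 1e-30) a = 0.0; }
    }
    snO *= am_step_dec;
    for (int i = 0; i < nPY; i++) {
      miniO_py[i] *= am_step_dec;
      if (miniO_py[i] < 1e-30) miniO_py[i] = 0.0;
    }
    for (int i = 0; i < nIN; i++) {
      miniO_in[i] *= am_step_dec;
      if (miniO_in[i] < 1e-30) miniO_in[i] = 0.0;
    }
    std::fill(gbcond_tc.begin(), gbcond_tc.end(), 0.0);
    for (auto &p : projs) {
      if (p.receptor != 3) continue;
      int ns = (int)p.Rg.size();
      for (int sidx = 0; sidx < ns; sidx++) {
        double R = p.Rg[sidx], G = p.Gg[sidx];
        G = G * gb_e4 + R * gb_c23;
        R *= gb_e2;
        p.Rg[sidx] = R; p.Gg[sidx] = G;
        if (G < 1e-6) continue;
        double g2 = G * G, g4 = g2 * g2;
        double gate = p.g * g4 / (g4 + gb_Kd);
        for (int c = p.offs[sidx]; c < p.offs[sidx + 1]; c++)
          gbcond_tc[p.tgt[c]] += gate;
      }
    }

    // --- collect per-target synaptic conductances (uS) --------------------
    // exc (E=0) and inh (E=-70) onto PY/IN dendrites; TC/RE below.
    double lfp_now = 0.0;

    // pre-zero accumulators built on the fly per cell from projection A's
    // projection lookup by (tgt_layer, receptor) is done once:
    // for speed, cache raw pointers
    // PY cells -------------------------------------------------------------
    {
      CortP &P = pyP;
      double gcp = P.Gds / P.aD;
      for (int i = 0; i < nPY; i++) {
        double vd = pyVD[i], vs = pyVS[i];
        double ge = mini_g_py * miniO_py[i];
        double gn = 0.0, gi = 0.0;
        for (int pi : by_tgt_layer[0]) {
          Proj &p = projs[pi];
          if (p.receptor == 0) ge += p.g * p.A[i];
          else if (p.receptor == 1) gn += p.g * p.A[i];
          else if (p.receptor == 2) gi += p.g * p.A[i];
        }
        gn *= tNmda.at(vd);
        double i_syn_nA = (ge + gn) * (vd - E_ampa) + gi * (vs - E_gabaa);
        lfp_now += i_syn_nA;

        // soma (quasi-stationary); GABA_A is perisomatic
        double sm = pySM[i], sh = pySH[i], snn = pySN_[i];
        double gna_se = P.gna_s * sm * sm * sm * sh;
        double gk_se = P.gk_s * snn;
        double gi_mS = gi * 1e-3;
        double vsi = vs;
        for (int it = 0; it < P.soma_iter; it++) {
          double gnap_se = P.gnap_s * tNap.at(vsi);
          double num = P.Gds * vd + gi_mS * E_gabaa +
                       P.aS * ((gna_se + gnap_se) * ENA + gk_se * EK);
          double den = P.Gds + gi_mS + P.aS * (gna_se + gnap_se + gk_se);
          double vn = num / den;
          if (std::fabs(vn - vsi) < 1e-6) { vsi = vn; break; }
          vsi = vn;
        }
        double vs_new = vsi;

        // dendrite
        double gna_de = P.gna_d * pyNaM[i] * pyNaM[i] * pyNaM[i] * pyNaH[i];
        double gnap_de = pyGNAP[i] * tNap.at(vd);
        double ghva_e = P.ghva * pyHvaM[i] * pyHvaM[i] * pyHvaH[i];
        double gk_slow = pyGKCA[i] * pyKcaM[i] + P.gkm * pyKmM[i];
        double G = pyGL[i] + pyGKL[i] + gna_de + gnap_de + ghva_e + gk_slow + gcp;
        double GE = pyGL[i] * pyEL[i] + (pyGKL[i] + gk_slow) * EK +
                    (gna_de + gnap_de) * ENA + ghva_e * ECA + gcp * vs_new;
        double sge = (ge + gn) * 1e-3 / P.aD;
        G += sge; GE += sge * E_ampa;
        double Eeff = GE / G;
        double vd_new = Eeff + (vd - Eeff) * std::exp(-dt * G / P.Cm);

        double ihva = ghva_e * (vd - ECA);
        pyCa[i] += dt * (-P.cainflux * ihva - (pyCa[i] - P.carest) / P.catau);
        if (pyCa[i] < 0) pyCa[i] = 0;

        {
          const double *r0, *r1; double f;
          tCD.locate(vd, r0, r1, f);
          MTab::upd(r0, r1, f, 0, pyNaM[i]);
          MTab::upd(r0, r1, f, 1, pyNaH[i]);
          MTab::upd(r0, r1, f, 2, pyKmM[i]);
          MTab::upd(r0, r1, f, 3, pyHvaM[i]);
          MTab::upd(r0, r1, f, 4, pyHvaH[i]);
          tCS.locate(vs_new, r0, r1, f);
          MTab::upd(r0, r1, f, 0, pySM[i]);
          MTab::upd(r0, r1, f, 1, pySH[i]);
          MTab::upd(r0, r1, f, 2, pySN_[i]);
        }
        { // KCa: small-z series for 1-exp(-dt/tau)
          double a = 0.01 * pyCa[i], b = 0.02;
          double z = dt * (a + b) * QT;
          double st = z * (1.0 - 0.5 * z);
          pyKcaM[i] += (a / (a + b) - pyKcaM[i]) * st;
        }

        bool spike = (vs < 0.0 && vs_new >= 0.0 && t - pyLast[i] > 1.0);
        pyVD[i] = vd_new; pyVS[i] = vs_new;
        if (spike) { pyLast[i] = t; on_spike(0, i); }
      }
    }
    // IN cells -------------------------------------------------------------
    {
      CortP &P = inP;
      double gcp = P.Gds / P.aD;
      for (int i = 0; i < nIN; i++) {
        double vd = inVD[i], vs = inVS[i];
        double ge = mini_g_in * miniO_in[i];
        double gn = 0.0, gi = 0.0;
        for (int pi : by_tgt_layer[1]) {
          Proj &p = projs[pi];
          if (p.receptor == 0) ge += p.g * p.A[i];
          else if (p.receptor == 1) gn += p.g * p.A[i];
          else if (p.receptor == 2) gi += p.g * p.A[i];
        }
        gn *= tNmda.at(vd);

        double sm = inSM[i], sh = inSH[i], snn = inSN_[i];
        double gna_se = P.gna_s * sm * sm * sm * sh;
        double gk_se = P.gk_s * snn;
        double vsi = vs;
        for (int it = 0; it < P.soma_iter; it++) {
          double num = P.Gds * vd + P.aS * (gna_se * ENA + gk_se * EK);
          double den = P.Gds + P.aS * (gna_se + gk_se);
          double vn = num / den;
          if (std::fabs(vn - vsi) < 1e-6) { vsi = vn; break; }
          vsi = vn;
        }
        double vs_new = vsi;

        double gna_de = P.gna_d * inNaM[i] * inNaM[i] * inNaM[i] * inNaH[i];
        double ghva_e = P.ghva * inHvaM[i] * inHvaM[i] * inHvaH[i];
        double gk_slow = inGKCA[i] * inKcaM[i] + P.gkm * inKmM[i];
        double G = inGL[i] + inGKL[i] + gna_de + ghva_e + gk_slow + gcp;
        double GE = inGL[i] * inEL[i] + (inGKL[i] + gk_slow) * EK + gna_de * ENA +
                    ghva_e * ECA + gcp * vs_new;
        double sge = (ge + gn) * 1e-3 / P.aD, sgi = gi * 1e-3 / P.aD;
        G += sge + sgi; GE += sge * E_ampa + sgi * E_gabaa;
        double Eeff = GE / G;
        double vd_new = Eeff + (vd - Eeff) * std::exp(-dt * G / P.Cm);

        double ihva = ghva_e * (vd - ECA);
        inCa[i] += dt * (-P.cainflux * ihva - (inCa[i] - P.carest) / P.catau);
        if (inCa[i] < 0) inCa[i] = 0;

        {
          const double *r0, *r1; double f;
          tCD.locate(vd, r0, r1, f);
          MTab::upd(r0, r1, f, 0, inNaM[i]);
          MTab::upd(r0, r1, f, 1, inNaH[i]);
          MTab::upd(r0, r1, f, 2, inKmM[i]);
          MTab::upd(r0, r1, f, 3, inHvaM[i]);
          MTab::upd(r0, r1, f, 4, inHvaH[i]);
          tCS.locate(vs_new, r0, r1, f);
          MTab::upd(r0, r1, f, 0, inSM[i]);
          MTab::upd(r0, r1, f, 1, inSH[i]);
          MTab::upd(r0, r1, f, 2, inSN_[i]);
        }
        {
          double a = 0.01 * inCa[i], b = 0.02;
          double z = dt * (a + b) * QT;
          double st = z * (1.0 - 0.5 * z);
          inKcaM[i] += (a / (a + b) - inKcaM[i]) * st;
        }

        bool spike = (vs < 0.0 && vs_new >= 0.0 && t - inLast[i] > 1.0);
        inVD[i] = vd_new; inVS[i] = vs_new;
        if (spike) { inLast[i] = t; on_spike(1, i); }
      }
    }
    // TC cells -------------------------------------------------------------
    {
      ThalP &P = tcP;
      for (int i = 0; i < nTC; i++) {
        double v = tcV[i];
        double ge = g_sn * snO, gi = 0.0, gb = gbcond_tc[i];
        for (int pi : by_tgt_layer[2]) {
          Proj &p = projs[pi];
          if (p.receptor == 0) ge += p.g * p.A[i];
          else if (p.receptor == 2) gi += p.g * p.A[i];
        }
        double gna_e = P.gna * tcNaM[i] * tcNaM[i] * tcNaM[i] * tcNaH[i];
        double n2 = tcKN[i] * tcKN[i], gk_e = P.gk * n2 * n2;
        double gt_e = tcGT[i] * tcTM[i] * tcTM[i] * tcTH[i];
        double gh_e = tcGH[i] * (tcO[i] + P.ginc * tcOL[i]);
        double G = tcGL[i] + tcGKL[i] + gna_e + gk_e + gt_e + gh_e;
        double GE = tcGL[i] * tcEL[i] + (tcGKL[i] + gk_e) * EK + gna_e * ENA +
                    gt_e * ECA + gh_e * EH;
        double sge = ge * 1e-3 / P.area, sgi = gi * 1e-3 / P.area,
               sgb = gb * 1e-3 / P.area;
        G += sge + sgi + sgb;
        GE += sge * E_ampa + sgi * E_gabaa_tc + sgb * EK;
        double Eeff = GE / G;
        double vnew = Eeff + (v - Eeff) * std::exp(-dt * G / P.Cm);

        double it_cur = gt_e * (v - ECA);
        tcCa[i] += dt * (-P.cainflux * it_cur - (tcCa[i] - P.carest) / P.catau);
        if (tcCa[i] < 0) tcCa[i] = 0;

        {
          const double *r0, *r1; double f;
          tTC.locate(v, r0, r1, f);
          MTab::upd(r0, r1, f, 0, tcNaM[i]);
          MTab::upd(r0, r1, f, 1, tcNaH[i]);
          MTab::upd(r0, r1, f, 2, tcKN[i]);
          MTab::upd(r0, r1, f, 3, tcTM[i]);
          MTab::upd(r0, r1, f, 4, tcTH[i]);
        }
        { // I_h scheme, Euler
          double hinfv = tIhInf.at(v), taus = tIhTau.at(v);
          double a = hinfv / taus, b = (1.0 - hinfv) / taus;
          double ca2 = tcCa[i] * tcCa[i], k1c = P.k1 * ca2 * ca2;
          double O = tcO[i], P1v = tcP1[i], OL = tcOL[i];
          double dO = a * (1 - O - OL) - b * O - P.k3 * O * P1v + P.k4 * OL;
          double dP1 = k1c * (1 - P1v) - P.k2 * P1v - P.k3 * O * P1v +
                       P.k4 * OL;
          double dOL = P.k3 * O * P1v - P.k4 * OL;
          O += dt * dO; P1v += dt * dP1; OL += dt * dOL;
          if (O < 0) O = 0; if (O > 1) O = 1;
          if (P1v < 0) P1v = 0; if (P1v > 1) P1v = 1;
          if (OL < 0) OL = 0; if (OL > 1) OL = 1;
          tcO[i] = O; tcP1[i] = P1v; tcOL[i] = OL;
        }
        bool spike = (v < 0.0 && vnew >= 0.0 && t - tcLast[i] > 1.0);
        tcV[i] = vnew;
        if (spike) { tcLast[i] = t; on_spike(2, i); }
      }
    }
    // RE cells -------------------------------------------------------------
    {
      ThalP &P = reP;
      for (int i = 0; i < nRE; i++) {
        double v = reV[i];
        double ge = 0.0, gi = 0.0;
        for (int pi : by_tgt_layer[3]) {
          Proj &p = projs[pi];
          if (p.receptor == 0) ge += p.g * p.A[i];
          else if (p.receptor == 2) gi += p.g * p.A[i];
        }
        double gna_e = P.gna * reNaM[i] * reNaM[i] * reNaM[i] * reNaH[i];
        double n2 = reKN[i] * reKN[i], gk_e = P.gk * n2 * n2;
        double gt_e = reGT[i] * reTM[i] * reTM[i] * reTH[i];
        double G = reGL[i] + reGKL[i] + gna_e + gk_e + gt_e;
        double GE = reGL[i] * reEL[i] + (reGKL[i] + gk_e) * EK + gna_e * ENA +
                    gt_e * ECA;
        double sge = ge * 1e-3 / P.area, sgi = gi * 1e-3 / P.area;
        G += sge + sgi;
        GE += sge * E_ampa + sgi * E_gabaa;
        double Eeff = GE / G;
        double vnew = Eeff + (v - Eeff) * std::exp(-dt * G / P.Cm);

        {
          const double *r0, *r1; double f;
          tRE.locate(v, r0, r1, f);
          MTab::upd(r0, r1, f, 0, reNaM[i]);
          MTab::upd(r0, r1, f, 1, reNaH[i]);
          MTab::upd(r0, r1, f, 2, reKN[i]);
          MTab::upd(r0, r1, f, 3, reTM[i]);
          MTab::upd(r0, r1, f, 4, reTH[i]);
        }

        bool spike = (v < 0.0 && vnew >= 0.0 && t - reLast[i] > 1.0);
        reV[i] = vnew;
        if (spike) { reLast[i] = t; on_spike(3, i); }
      }
    }

    // --- detector arming / per-ms bookkeeping -----------------------------
    if (t - last_py_spk > det_silence) {
      if (!armed) {
        armed = true; cnt = 0; silence_from = last_py_spk;
        if (p4_track) p4_track = false;
      } else if (cnt > 0) {
        // renewed silence while counting: a fresh Down state
        cnt = 0; silence_from = last_py_spk;
      }
    }
    if (step >= next_ms_step) {           // once per ms
      next_ms_step += ms_stride;
      int tot = 0;
      for (int b : p4_bins) tot += b;
      double rate = tot * 1000.0 / p4_win_ms;  // population spikes/s
      if (p4_track) {
        if (rate > p4_peak) p4_peak = rate;
        if (p4_peak >= p4_min && rate < p4_frac * p4_peak) {
          ev.add(t, 5 /*UP_FALL*/, 4, p4_peak);
          p4_track = false;
          if (point == 4) trigger_protocol(t);
        }
      }
      p4_bin_pos = (p4_bin_pos + 1) % p4_win_ms;
      p4_bins[p4_bin_pos] = 0;
    }

    // --- recording / safety ----------------------------------------------
    if (step % rec_stride == 0) {
      lfp.push_back(-lfp_now);
      int k = 0;
      for (int j = 0; j < rec_py.size(); j++) traces[k++].push_back(pyVD[rec_py[j]]);
      for (int j = 0; j < rec_in.size(); j++) traces[k++].push_back(inVD[rec_in[j]]);
      for (int j = 0; j < rec_tc.size(); j++) traces[k++].push_back(tcV[rec_tc[j]]);
      for (int j = 0; j < rec_re.size(); j++) traces[k++].push_back(reV[rec_re[j]]);
    }
    if (step % check_stride == 0) {
      for (int i = 0; i < nPY; i++)
        if (!std::isfinite(pyVD[i]) || std::fabs(pyVD[i]) > 200.0)
          stop("numerical divergence at t=%.2f ms in PY cell %d", t, i + 1);
      for (int i = 0; i < nTC; i++)
        if (!std::isfinite(tcV[i]) || std::fabs(tcV[i]) > 200.0)
          stop("numerical divergence at t=%.2f ms in TC cell %d", t, i + 1);
      Rcpp::checkUserInterrupt();
    }
  }
}

List NetSim::result() {
  int ntr = (int)traces.size();
  List trl(ntr);
  for (int i = 0; i < ntr; i++) trl[i] = NumericVector(traces[i].begin(),
                                                       traces[i].end());
  return List::create(
      _["lfp"] = NumericVector(lfp.begin(), lfp.end()),
      _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["spike_layer"] = IntegerVector(spk_layer.begin(), spk_layer.end()),
      _["spike_idx"] = IntegerVector(spk_idx.begin(), spk_idx.end()),
      _["event_t"] = NumericVector(ev.t.begin(), ev.t.end()),
      _["event_kind"] = IntegerVector(ev.kind.begin(), ev.kind.end()),
      _["event_point"] = IntegerVector(ev.point.begin(), ev.point.end()),
      _["event_aux"] = NumericVector(ev.aux.begin(), ev.aux.end()),
      _["traces"] = trl);
}

// [[Rcpp::export]]
List cpp_run_network(List cfg) {
  NetSim sim;
  sim.setup(cfg);
  sim.run();
  return sim.result();
}
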
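// Monodomain kernel: Courtemanche-Ramirez-Nattel (1998) human atrial
// ionic model with AF remodelling scales and an acetylcholine-activated
// K+ current, integrated by Rush-Larsen (gates) + forward Euler (V and
// concentrations), with a 7-point no-flux Laplacian by the method of
// weights.  Voltage-dependent rate expressions are tabulated per (dt,
// params) on a fine V grid; the scalar reference path (crn_currents_cpp)
// evaluates everything directly and serves as the in-package oracle for
// the tabulated path.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// ---- physical constants (CRN 1998) ------------------------------------
static const double P_R   = 8.3143;     // J mol^-1 K^-1
static const double P_T   = 310.0;      // K
static const double P_F   = 96.4867;    // C mmol^-1
static const double RTF   = P_R * P_T / P_F;  // 26.712... mV
static const double V_i   = 13668.0;    // um^3
static const double V_up  = 1109.52;
static const double V_rel = 96.48;
static const double K_o   = 5.4;        // mM
static const double Na_o  = 140.0;
static const double Ca_o  = 1.8;
static const double g_Na  = 7.8;        // nS/pF
static const double g_K1  = 0.09;
static const double g_to  = 0.1652;
static const double g_Kr  = 0.029411765;
static const double g_Ks  = 0.12941176;
static const double g_CaL = 0.12375;
static const double g_bCa = 0.001131;
static const double g_bNa = 0.0006744375;
static const double i_NaK_max  = 0.59933874; // pA/pF
static const double i_NaCa_max = 1600.0;     // pA/pF
static const double i_pCa_max  = 0.275;      // pA/pF
static const double Km_Na_i = 10.0;
static const double Km_K_o  = 1.5;
static const double Km_Na   = 87.5;
static const double Km_Ca   = 1.38;
static const double k_sat   = 0.1;
static const double gma     = 0.35;
static const double k_rel   = 30.0;     // ms^-1
static const double tau_tr  = 180.0;    // ms
static const double I_up_max = 0.005;   // mM/ms
static const double K_up     = 0.00092;
static const double Ca_up_max = 15.0;
static const double CMDN_max = 0.05;
static const double TRPN_max = 0.07;
static const double CSQN_max = 10.0;
static const double Km_CMDN  = 0.00238;
static const double Km_TRPN  = 0.0005;
static const double Km_CSQN  = 0.8;
static const double K_Q10    = 3.0;
static const double tau_u    = 8.0;
static const double tau_fca  = 2.0;

// state variable order (21)
enum { S_V = 0, S_m, S_h, S_j, S_oa, S_oi, S_ua, S_ui, S_xr, S_xs,
       S_d, S_f, S_fca, S_u, S_v, S_w, S_Nai, S_Ki, S_Cai, S_Caup,
       S_Carel, NSTATE };

struct Params {
  double sCaL, sKr, sKs, ach, ach_exp, cach_off, cach_amp, Cm, oach;
};

static Params params_from_list(List p) {
  Params q;
  q.sCaL = as<double>(p["scale_gCaL"]);
  q.sKr  = as<double>(p["scale_gKr"]);
  q.sKs  = as<double>(p["scale_gKs"]);
  q.ach  = as<double>(p["ach"]);
  q.ach_exp  = as<double>(p["ach_exponent"]);
  q.cach_off = as<double>(p["cach_offset"]);
  q.cach_amp = as<double>(p["cach_amp"]);
  q.Cm   = as<double>(p["Cm"]);
  q.oach = (q.ach > 0.0) ? 10.0 / (1.0 + 9.13 / std::pow(q.ach, q.ach_exp))
                         : 0.0;
  return q;
}

// ---- voltage-dependent rate expressions (scalar forms) -----------------
// Each returns steady state and time constant for one gate at V.
static inline void rate_m(double V, double &inf, double &tau) {
  double a = (std::fabs(V + 47.13) < 1e-7)
               ? 3.2
               : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double b = 0.08 * std::exp(-V / 11.0);
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static inline void rate_h(double V, double &inf, double &tau) {
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static inline void rate_j(double V, double &inf, double &tau) {
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
        * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static inline void rate_oa(double V, double &inf, double &tau) {
  double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau = 1.0 / ((a + b) * K_Q10);
  inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
}
static inline void rate_oi(double V, double &inf, double &tau) {
  double a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  tau = 1.0 / ((a + b) * K_Q10);
  inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
}
static inline void rate_ua(double V, double &inf, double &tau) {
  double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau = 1.0 / ((a + b) * K_Q10);
  inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
}
static inline void rate_ui(double V, double &inf, double &tau) {
  double a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double b = std::exp((V - 158.0) / 16.0);
  tau = 1.0 / ((a + b) * K_Q10);
  inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
}
static inline void rate_xr(double V, double &inf, double &tau) {
  double a = (std::fabs(V + 14.1) < 1e-7)
               ? 0.0015
               : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double b = (std::fabs(V - 3.3328) < 1e-7)
               ? 7.3898e-5 * 5.1237
               : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  tau = 1.0 / (a + b);
  inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
}
static inline void rate_xs(double V, double &inf, double &tau) {
  double a = (std::fabs(V - 19.9) < 1e-7)
               ? 0.00068
               : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double b = (std::fabs(V - 19.9) < 1e-7)
               ? 0.000315
               : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  tau = 0.5 / (a + b);
  inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
}
static inline void rate_d(double V, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  double a = (V + 10.0) / 6.24;
  if (std::fabs(a) < 1e-7) {
    tau = 4.579 / (1.0 + std::exp(-(V + 10.0) / 6.24)) / 2.0 * 2.0; // = 2.2895
    tau = 2.2895;
  } else {
    double e = std::exp(-a);
    tau = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
}
static inline void rate_f(double V, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  double x = 0.0337 * (V + 10.0);
  tau = 9.0 / (0.0197 * std::exp(-x * x) + 0.02);
}
static inline void rate_w(double V, double &inf, double &tau) {
  double b = (V - 7.9) / 5.0;
  if (std::fabs(b) < 1e-7) {
    tau = 6.0 * 0.2 / 1.3;
  } else {
    double e = std::exp(-b);
    tau = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
  inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

// ---- lookup tables -----------------------------------------------------
static const double TAB_VMIN = -120.0, TAB_VMAX = 80.0, TAB_DV = 0.05;
static const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;
static const int NVGATE = 12; // m h j oa oi ua ui xr xs d f w
// interleaved row layout per V index (padded to 32 for alignment):
// [0..11] gate inf, [12..23] gate rl = exp(-dt/tau), [24] ik1c, [25] gkur,
// [26] ikrc, [27] fnak, [28] naca1, [29] naca2, [30] cach
static const int TAB_STRIDE = 32;

struct Tables {
  double dt, cach_off, cach_amp;
  std::vector<double> tt; // TAB_N * TAB_STRIDE interleaved
  double rl_fca, rl_u;
  bool valid;
  Tables() : valid(false) {}
};
static Tables g_tab;

typedef void (*RateFn)(double, double &, double &);
static RateFn RATES[NVGATE] = { rate_m, rate_h, rate_j, rate_oa, rate_oi,
                                rate_ua, rate_ui, rate_xr, rate_xs,
                                rate_d, rate_f, rate_w };

static void build_tables(double dt, const Params &P) {
  if (g_tab.valid && g_tab.dt == dt && g_tab.cach_off == P.cach_off &&
      g_tab.cach_amp == P.cach_amp)
    return;
  double sigma = (std::exp(Na_o / 67.3) - 1.0) / 7.0;
  g_tab.tt.assign((size_t)TAB_N * TAB_STRIDE, 0.0);
  for (int i = 0; i < TAB_N; ++i) {
    double V = TAB_VMIN + i * TAB_DV;
    double *row = &g_tab.tt[(size_t)i * TAB_STRIDE];
    for (int g = 0; g < NVGATE; ++g) {
      double inf, tau;
      RATES[g](V, inf, tau);
      row[g] = inf;
      row[NVGATE + g] = std::exp(-dt / tau);
    }
    row[24] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
    row[25] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
    row[26] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
    double fvrt = V / RTF;
    row[27] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * fvrt)
                     + 0.0365 * sigma * std::exp(-fvrt));
    row[28] = std::exp(gma * fvrt);
    row[29] = std::exp((gma - 1.0) * fvrt);
    row[30] = P.cach_off + P.cach_amp / (1.0 + std::exp((V + 59.53) / 17.18));
  }
  g_tab.rl_fca = std::exp(-dt / tau_fca);
  g_tab.rl_u   = std::exp(-dt / tau_u);
  g_tab.dt = dt; g_tab.cach_off = P.cach_off; g_tab.cach_amp = P.cach_amp;
  g_tab.valid = true;
}

static inline double sigmoid_clamped(double a) {
  if (a > 40.0) return 1.0;
  if (a < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-a));
}

// exp(-x) for small positive x (dt/tau with tau >= ~1.9 ms)
static inline double exp_neg_small(double x) {
  return 1.0 - x + 0.5 * x * x - x * x * x / 6.0;
}

// ---- one ionic step (tabulated path) -----------------------------------
// Advances gates + concentrations of cell arrays at index i in place and
// returns Iion in pA/pF (positive = outward).  Vm is NOT updated here.
static const int CELL_STRIDE = 24; // 21 states + cached ENa, EK, ECa
static const int C_ENa = 21, C_EK = 22, C_ECa = 23;

static inline double ionic_step(double Vm, double *cs,
                                const Params &P, const Tables &T,
                                bool update_nernst) {
  // table row
  double u = (Vm - TAB_VMIN) / TAB_DV;
  if (u < 0.0) u = 0.0;
  if (u > TAB_N - 1.001) u = TAB_N - 1.001;
  int k = (int)u;
  double fr = u - k;
  const double *r0 = &T.tt[(size_t)k * TAB_STRIDE];
  const double *r1 = r0 + TAB_STRIDE;

#define LKP(q) (r0[q] + fr * (r1[q] - r0[q]))

  double Nai = cs[S_Nai], Ki = cs[S_Ki], Cai = cs[S_Cai];
  double Caup = cs[S_Caup], Carel = cs[S_Carel];

  if (update_nernst) {
    cs[C_ENa] = RTF * std::log(Na_o / Nai);
    cs[C_EK]  = RTF * std::log(K_o / Ki);
    cs[C_ECa] = 0.5 * RTF * std::log(Ca_o / Cai);
  }
  double ENa = cs[C_ENa], EK = cs[C_EK], ECa = cs[C_ECa];

  double m = cs[S_m], h = cs[S_h], j = cs[S_j];
  double oa = cs[S_oa], oi = cs[S_oi];
  double ua = cs[S_ua], ui = cs[S_ui];
  double xr = cs[S_xr], xs = cs[S_xs];
  double d = cs[S_d], f = cs[S_f], fca = cs[S_fca];
  double ug = cs[S_u], vg = cs[S_v], wg = cs[S_w];

  // membrane currents (pA/pF)
  double iNa  = g_Na * m * m * m * h * j * (Vm - ENa);
  double iK1  = g_K1 * LKP(24) * (Vm - EK);
  double ito  = g_to * oa * oa * oa * oi * (Vm - EK);
  double ikur = LKP(25) * ua * ua * ua * ui * (Vm - EK);
  double ikr  = P.sKr * g_Kr * LKP(26) * xr * (Vm - EK);
  double iks  = P.sKs * g_Ks * xs * xs * (Vm - EK);
  double ical = P.sCaL * g_CaL * d * f * fca * (Vm - 65.0);
  double tnak = Km_Na_i / Nai;
  double inak = i_NaK_max * LKP(27)
    / (1.0 + tnak * std::sqrt(tnak)) * (K_o / (K_o + Km_K_o));
  double n1 = LKP(28), n2 = LKP(29);
  double inaca = i_NaCa_max
    * (n1 * Nai * Nai * Nai * Ca_o - n2 * Na_o * Na_o * Na_o * Cai)
    / ((Km_Na * Km_Na * Km_Na + Na_o * Na_o * Na_o) * (Km_Ca + Ca_o)
       * (1.0 + k_sat * n2));
  double ibna = g_bNa * (Vm - ENa);
  double ibca = g_bCa * (Vm - ECa);
  double ipca = i_pCa_max * Cai / (0.0005 + Cai);
  double ikach = P.oach * LKP(30) * (Vm - EK);

  double Iion = iNa + iK1 + ito + ikur + ikr + iks + ical + inak + inaca
              + ibna + ibca + ipca + ikach;

  // Ca handling fluxes (mM/ms)
  double irel = k_rel * ug * ug * vg * wg * (Carel - Cai);
  double itr  = (Caup - Carel) / tau_tr;
  double iup  = I_up_max / (1.0 + K_up / Cai);
  double iupl = I_up_max * Caup / Ca_up_max;
  double Fn = 1e3 * (1e-15 * V_rel * irel
                     - (1e-15 / (2.0 * P_F))
                       * (0.5 * ical * P.Cm - 0.2 * inaca * P.Cm));

  // gate updates: 12 tabulated V-gates (Rush-Larsen)
  const double dt = T.dt;
  {
    double inf, rl;
#define RLUP(slot, gq) \
    inf = LKP(gq); rl = LKP(NVGATE + gq); \
    cs[slot] = inf + (cs[slot] - inf) * rl;
    RLUP(S_m, 0) RLUP(S_h, 1) RLUP(S_j, 2) RLUP(S_oa, 3) RLUP(S_oi, 4)
    RLUP(S_ua, 5) RLUP(S_ui, 6) RLUP(S_xr, 7) RLUP(S_xs, 8) RLUP(S_d, 9)
    RLUP(S_f, 10) RLUP(S_w, 11)
#undef RLUP
  }
  // fCa, u, v gates (Ca/Fn dependent)
  {
    double inf = 1.0 / (1.0 + Cai / 0.00035);
    cs[S_fca] = inf + (fca - inf) * T.rl_fca;
  }
  double au = (Fn - 3.4175e-13) / 13.67e-16;
  double su = sigmoid_clamped(au);
  cs[S_u] = su + (ug - su) * T.rl_u;
  {
    double av = (Fn - 6.835e-14) / 13.67e-16;
    double vinf = 1.0 - sigmoid_clamped(av);
    double tauv = 1.91 + 2.09 * su;
    double rlv = exp_neg_small(dt / tauv);
    cs[S_v] = vinf + (vg - vinf) * rlv;
  }

  // concentrations (forward Euler), currents converted to pA via Cm
  double Cm = P.Cm;
  double dNai = (-3.0 * inak - (3.0 * inaca + ibna + iNa)) * Cm / (V_i * P_F);
  double dKi  = (2.0 * inak - (iK1 + ito + ikur + ikr + iks + ikach)) * Cm
                / (V_i * P_F);
  double b1 = (2.0 * inaca - (ipca + ical + ibca)) * Cm / (2.0 * V_i * P_F)
            + (V_up * (iupl - iup) + irel * V_rel) / V_i;
  double t1 = Cai + Km_TRPN, t2 = Cai + Km_CMDN;
  double b2 = 1.0 + TRPN_max * Km_TRPN / (t1 * t1)
            + CMDN_max * Km_CMDN / (t2 * t2);
  double t3 = Carel + Km_CSQN;
  double dCarel = (itr - irel) / (1.0 + CSQN_max * Km_CSQN / (t3 * t3));
  double dCaup  = iup - iupl - itr * V_rel / V_up;

  cs[S_Nai]   = Nai + dt * dNai;
  cs[S_Ki]    = Ki + dt * dKi;
  cs[S_Cai]   = Cai + dt * b1 / b2;
  cs[S_Caup]  = Caup + dt * dCaup;
  cs[S_Carel] = Carel + dt * dCarel;
#undef LKP
  return Iion;
}

// ---- scalar reference path: all currents at one state ------------------
// [[Rcpp::export]]
NumericVector crn_currents_cpp(NumericVector state, List params) {
  Params P = params_from_list(params);
  double Vm = state[S_V];
  double Nai = state[S_Nai], Ki = state[S_Ki], Cai = state[S_Cai];
  double ENa = RTF * std::log(Na_o / Nai);
  double EK  = RTF * std::log(K_o / Ki);
  double ECa = 0.5 * RTF * std::log(Ca_o / Cai);
  double sigma = (std::exp(Na_o / 67.3) - 1.0) / 7.0;
  double fvrt = Vm / RTF;
  double m = state[S_m], h = state[S_h], j = state[S_j];
  double iNa  = g_Na * m * m * m * h * j * (Vm - ENa);
  double iK1  = g_K1 * (Vm - EK) / (1.0 + std::exp(0.07 * (Vm + 80.0)));
  double ito  = g_to * std::pow(state[S_oa], 3) * state[S_oi] * (Vm - EK);
  double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(Vm - 15.0) / 13.0));
  double ikur = gkur * std::pow(state[S_ua], 3) * state[S_ui] * (Vm - EK);
  double ikr  = P.sKr * g_Kr * state[S_xr] * (Vm - EK)
                / (1.0 + std::exp((Vm + 15.0) / 22.4));
  double iks  = P.sKs * g_Ks * state[S_xs] * state[S_xs] * (Vm - EK);
  double ical = P.sCaL * g_CaL * state[S_d] * state[S_f] * state[S_fca]
                * (Vm - 65.0);
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * fvrt)
                       + 0.0365 * sigma * std::exp(-fvrt));
  double inak = i_NaK_max * fnak / (1.0 + std::pow(Km_Na_i / Nai, 1.5))
                * (K_o / (K_o + Km_K_o));
  double n2 = std::exp((gma - 1.0) * fvrt);
  double inaca = i_NaCa_max
    * (std::exp(gma * fvrt) * Nai * Nai * Nai * Ca_o
       - n2 * Na_o * Na_o * Na_o * Cai)
    / ((std::pow(Km_Na, 3) + std::pow(Na_o, 3)) * (Km_Ca + Ca_o)
       * (1.0 + k_sat * n2));
  double ibna = g_bNa * (Vm - ENa);
  double ibca = g_bCa * (Vm - ECa);
  double ipca = i_pCa_max * Cai / (0.0005 + Cai);
  double cach = P.cach_off + P.cach_amp / (1.0 + std::exp((Vm + 59.53) / 17.18));
  double ikach = P.oach * cach * (Vm - EK);
  // pA (multiply pA/pF by Cm)
  NumericVector out = NumericVector::create(
    _["I_Na"] = iNa * P.Cm, _["I_K1"] = iK1 * P.Cm, _["I_to"] = ito * P.Cm,
    _["I_Kur"] = ikur * P.Cm, _["I_Kr"] = ikr * P.Cm, _["I_Ks"] = iks * P.Cm,
    _["I_CaL"] = ical * P.Cm, _["I_NaK"] = inak * P.Cm,
    _["I_NaCa"] = inaca * P.Cm, _["I_bNa"] = ibna * P.Cm,
    _["I_bCa"] = ibca * P.Cm, _["I_pCa"] = ipca * P.Cm,
    _["I_KACh"] = ikach * P.Cm);
  out.attr("E_Na") = ENa; out.attr("E_K") = EK; out.attr("E_Ca") = ECa;
  return out;
}

// ---- main engine -------------------------------------------------------
// init:  N x 21 state matrix (column per variable)
// nbr:   N x 6 integer matrix of 0-based neighbour indices, -1 = absent
// stim:  periodic pulse train applied to stim_idx (0-based), amplitude in
//        pA (divided by Cm internally; negative = depolarising)
// [[Rcpp::export]]
List sim_run_cpp(NumericMatrix init, IntegerMatrix nbr, double dx, double D,
                 double dt, double duration, List params,
                 IntegerVector stim_idx, double stim_amp, double stim_start,
                 double stim_period, double stim_dur, int stim_n,
                 IntegerVector probe_idx, double probe_dt,
                 int state_probe_idx, double state_probe_dt,
                 double snapshot_dt, bool record_snapshots,
                 bool record_activation, double act_threshold, int act_max,
                 int nernst_every) {
  const int N = init.nrow();
  if (init.ncol() != NSTATE) stop("state matrix must have 21 columns");
  Params P = params_from_list(params);
  build_tables(dt, P);
  const Tables &T = g_tab;

  // working state: per-cell contiguous layout (21 states + 3 Nernst)
  std::vector<double> S((size_t)N * CELL_STRIDE);
  for (int i = 0; i < N; ++i)
    for (int v = 0; v < NSTATE; ++v)
      S[(size_t)i * CELL_STRIDE + v] = init(i, v);
  std::vector<double> Vold(N), Vnew(N);
  for (int i = 0; i < N; ++i) Vold[i] = init(i, S_V);

  const double inv_dx2 = 1.0 / (dx * dx);
  const long n_steps = (long)std::floor(duration / dt + 0.5);

  // recording setup
  const long probe_every = probe_dt > 0 ? (long)std::floor(probe_dt / dt + 0.5) : 0;
  const long sprobe_every = state_probe_dt > 0
      ? (long)std::floor(state_probe_dt / dt + 0.5) : 0;
  const long snap_every = snapshot_dt > 0
      ? (long)std::floor(snapshot_dt / dt + 0.5) : 0;
  const int n_probe = probe_idx.size();
  const long n_probe_samp = probe_every > 0 ? n_steps / probe_every + 1 : 0;
  const long n_sprobe_samp = sprobe_every > 0 ? n_steps / sprobe_every + 1 : 0;
  const long n_snap = (record_snapshots && snap_every > 0)
      ? n_steps / snap_every + 1 : (record_snapshots ? 1 : 0);

  NumericMatrix probeV(n_probe_samp > 0 ? n_probe_samp : 0, n_probe);
  NumericVector probe_t(n_probe_samp > 0 ? n_probe_samp : 0);
  NumericMatrix sprobe(n_sprobe_samp > 0 ? n_sprobe_samp : 0,
                       state_probe_idx >= 0 ? NSTATE : 0);
  NumericVector sprobe_t(n_sprobe_samp > 0 ? n_sprobe_samp : 0);
  NumericMatrix snapV(record_snapshots ? N : 0, n_snap);
  NumericMatrix snapOi(record_snapshots ? N : 0, n_snap);
  NumericVector snap_t(n_snap);
  NumericMatrix act(record_activation ? N : 0, record_activation ? act_max : 0);
  IntegerVector act_n(record_activation ? N : 0);

  long ip = 0, isp = 0, isnap = 0;
  // sample initial condition (t = 0)
  if (probe_every > 0) {
    probe_t[ip] = 0.0;
    for (int p = 0; p < n_probe; ++p) probeV(ip, p) = Vold[probe_idx[p]];
    ++ip;
  }
  if (sprobe_every > 0 && state_probe_idx >= 0) {
    sprobe_t[isp] = 0.0;
    for (int v = 0; v < NSTATE; ++v)
      sprobe(isp, v) = S[(size_t)state_probe_idx * CELL_STRIDE + v];
    sprobe(isp, S_V) = Vold[state_probe_idx];
    ++isp;
  }
  if (record_snapshots) {
    snap_t[isnap] = 0.0;
    for (int i = 0; i < N; ++i) {
      snapV(i, 0) = Vold[i];
      snapOi(i, 0) = S[(size_t)i * CELL_STRIDE + S_oi];
    }
    ++isnap;
  }

  std::vector<char> is_stim(N, 0);
  for (int k = 0; k < stim_idx.size(); ++k) is_stim[stim_idx[k]] = 1;
  const double stim_per_pF = stim_amp / P.Cm;
  const bool any_stim = stim_idx.size() > 0 && stim_n > 0;

  // contiguous per-cell neighbour lists
  std::vector<int> nbrT((size_t)6 * N);
  for (int i = 0; i < N; ++i)
    for (int kk = 0; kk < 6; ++kk) nbrT[(size_t)6 * i + kk] = nbr(i, kk);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    bool upd_nernst = (step % nernst_every) == 0;

    // stimulus window?
    bool stim_on = false;
    if (any_stim && t >= stim_start - 1e-9) {
      double rel = t - stim_start;
      long pulse = stim_period > 0 ? (long)std::floor(rel / stim_period) : 0;
      if (pulse < stim_n) {
        double ph = rel - pulse * (stim_period > 0 ? stim_period : 0.0);
        if (ph < stim_dur - 1e-9) stim_on = true;
      }
    }

    const double *Vo = Vold.data();
    double *Vn = Vnew.data();
    const int *NB = nbrT.data();
    for (int i = 0; i < N; ++i) {
      double Vm = Vo[i];
      double Iion = ionic_step(Vm, &S[(size_t)i * CELL_STRIDE], P, T, upd_nernst);
      double lap = 0.0;
      int cnt = 0;
      const int *nb = NB + (size_t)6 * i;
      for (int kk = 0; kk < 6; ++kk) {
        int q = nb[kk];
        if (q >= 0) { lap += Vo[q]; ++cnt; }
      }
      lap = (lap - cnt * Vm) * inv_dx2;
      double dv = -Iion + D * lap;
      if (stim_on && is_stim[i]) dv -= stim_per_pF;
      Vn[i] = Vm + dt * dv;
      if (record_activation) {
        if (Vm < act_threshold && Vn[i] >= act_threshold) {
          int c = act_n[i];
          if (c < act_max) {
            act(i, c) = t + dt * (act_threshold - Vm) / (Vn[i] - Vm);
            act_n[i] = c + 1;
          }
        }
      }
    }
    std::swap(Vold, Vnew);

    const long s1 = step + 1;
    if (probe_every > 0 && s1 % probe_every == 0 && ip < n_probe_samp) {
      probe_t[ip] = s1 * dt;
      for (int p = 0; p < n_probe; ++p) probeV(ip, p) = Vold[probe_idx[p]];
      ++ip;
    }
    if (sprobe_every > 0 && state_probe_idx >= 0 && s1 % sprobe_every == 0 &&
        isp < n_sprobe_samp) {
      sprobe_t[isp] = s1 * dt;
      for (int v = 0; v < NSTATE; ++v)
      sprobe(isp, v) = S[(size_t)state_probe_idx * CELL_STRIDE + v];
      sprobe(isp, S_V) = Vold[state_probe_idx];
      ++isp;
    }
    if (record_snapshots && snap_every > 0 && s1 % snap_every == 0 &&
        isnap < n_snap) {
      snap_t[isnap] = s1 * dt;
      for (int i = 0; i < N; ++i) {
        snapV(i, isnap) = Vold[i];
        snapOi(i, isnap) = S[(size_t)i * CELL_STRIDE + S_oi];
      }
      ++isnap;
    }
    if (s1 % 10000 == 0) { // every 100 ms at dt = 0.01: sanity + interrupt
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(Vold[i]))
          stop("numerical failure (non-finite V) at voxel %d, t = %.2f ms",
               i + 1, s1 * dt);
      Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix st(N, NSTATE);
  for (int i = 0; i < N; ++i) {
    if (!std::isfinite(Vold[i]))
      stop("numerical failure (non-finite V) at voxel %d at end of run", i + 1);
    for (int v = 0; v < NSTATE; ++v) st(i, v) = S[(size_t)i * CELL_STRIDE + v];
    st(i, S_V) = Vold[i];
  }
  colnames(st) = CharacterVector::create(
    "V","m","h","j","oa","oi","ua","ui","xr","xs","d","f","fCa","u","v","w",
    "Na_i","K_i","Ca_i","Ca_up","Ca_rel");

  List out = List::create(
    _["final_state"] = st,
    _["probe_t"] = probe_t, _["probe_V"] = probeV,
    _["state_probe_t"] = sprobe_t, _["state_probe"] = sprobe,
    _["snap_t"] = snap_t, _["snap_V"] = snapV, _["snap_oi"] = snapOi,
    _["t_end"] = n_steps * dt);
  if (record_activation) {
    out["act_times"] = act;
    out["act_count"] = act_n;
  }
  return out;
}

// ---- filament extraction ----------------------------------------------
// Marching-tetrahedra broken-line method: each grid cube is split into 6
// Kuhn tetrahedra sharing the (0,0,0)-(1,1,1) diagonal; within a tet both
// fields are linear, so each isosurface is a plane and their intersection
// a segment clipped to the tet.  Faces of adjacent cubes receive the same
// diagonal, so segments meet without cracks.
static const int PERMS[6][3] = { {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0} };

// [[Rcpp::export]]
NumericMatrix filament_segments_cpp(NumericVector V3, NumericVector O3,
                                    IntegerVector dims, double dx,
                                    NumericVector origin,
                                    double viso, double oiso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *V = V3.begin();
  const double *O = O3.begin();
  std::vector<double> segs;

  int corn[8][3];
  for (int c = 0; c < 8; ++c) {
    corn[c][0] = c & 1; corn[c][1] = (c >> 1) & 1; corn[c][2] = (c >> 2) & 1;
  }
  // per-permutation tet corner ids (bit codes)
  int tets[6][4];
  for (int p = 0; p < 6; ++p) {
    int v = 0;
    tets[p][0] = 0;
    for (int s = 0; s < 3; ++s) {
      v |= 1 << PERMS[p][s];
      tets[p][s + 1] = v;
    }
  }

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double cv[8], co[8];
        bool ok = true;
        double vmin = 1e300, vmax = -1e300, omin = 1e300, omax = -1e300;
        for (int c = 0; c < 8 && ok; ++c) {
          int ii = i + corn[c][0], jj = j + corn[c][1], kk = k + corn[c][2];
          double vv = V[ii + (long)nx * (jj + (long)ny * kk)];
          double oo = O[ii + (long)nx * (jj + (long)ny * kk)];
          if (!std::isfinite(vv) || !std::isfinite(oo)) ok = false;
          cv[c] = vv - viso; co[c] = oo - oiso;
          if (cv[c] < vmin) vmin = cv[c];
          if (cv[c] > vmax) vmax = cv[c];
          if (co[c] < omin) omin = co[c];
          if (co[c] > omax) omax = co[c];
        }
        if (!ok || vmin > 0 || vmax < 0 || omin > 0 || omax < 0) continue;

        for (int p = 0; p < 6; ++p) {
          double a0 = cv[tets[p][0]], b0 = co[tets[p][0]];
          double gA[3], gB[3];
          for (int s = 0; s < 3; ++s) {
            gA[s] = cv[tets[p][s + 1]] - a0;
            gB[s] = co[tets[p][s + 1]] - b0;
          }
          // tet-level sign reject
          {
            double amn = a0, amx = a0, bmn = b0, bmx = b0;
            for (int s = 0; s < 3; ++s) {
              double av = cv[tets[p][s + 1]], bv = co[tets[p][s + 1]];
              if (av < amn) amn = av; if (av > amx) amx = av;
              if (bv < bmn) bmn = bv; if (bv > bmx) bmx = bv;
            }
            if (amn > 0 || amx < 0 || bmn > 0 || bmx < 0) continue;
          }
          // line of intersection of {a0 + gA.l = 0} and {b0 + gB.l = 0}
          double dir[3] = { gA[1] * gB[2] - gA[2] * gB[1],
                            gA[2] * gB[0] - gA[0] * gB[2],
                            gA[0] * gB[1] - gA[1] * gB[0] };
          double dn = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
          double ga2 = gA[0]*gA[0]+gA[1]*gA[1]+gA[2]*gA[2];
          double gb2 = gB[0]*gB[0]+gB[1]*gB[1]+gB[2]*gB[2];
          if (dn < 1e-12 * std::sqrt(ga2 * gb2) || ga2 == 0 || gb2 == 0)
            continue; // parallel or degenerate gradients
          double gab = gA[0]*gB[0]+gA[1]*gB[1]+gA[2]*gB[2];
          double det = ga2 * gb2 - gab * gab;
          double xq = (-a0 * gb2 + b0 * gab) / det;
          double yq = (-b0 * ga2 + a0 * gab) / det;
          double l0[3] = { xq * gA[0] + yq * gB[0],
                           xq * gA[1] + yq * gB[1],
                           xq * gA[2] + yq * gB[2] };
          // clip l(t) = l0 + t*dir to the simplex
          double tmin = -1e30, tmax = 1e30;
          bool feas = true;
          const double C[4][4] = { {1,0,0,0},{0,1,0,0},{0,0,1,0},{-1,-1,-1,1} };
          for (int c = 0; c < 4 && feas; ++c) {
            double val = C[c][0]*l0[0] + C[c][1]*l0[1] + C[c][2]*l0[2] + C[c][3];
            double dv  = C[c][0]*dir[0] + C[c][1]*dir[1] + C[c][2]*dir[2];
            if (std::fabs(dv) < 1e-14) {
              if (val < -1e-12) feas = false;
            } else if (dv > 0) {
              double tb = -val / dv; if (tb > tmin) tmin = tb;
            } else {
              double tb = -val / dv; if (tb < tmax) tmax = tb;
            }
          }
          if (!feas || tmax <= tmin + 1e-12) continue;
          double pts[2][3];
          for (int e = 0; e < 2; ++e) {
            double tt = e == 0 ? tmin : tmax;
            double l[3] = { l0[0] + tt * dir[0], l0[1] + tt * dir[1],
                            l0[2] + tt * dir[2] };
            for (int s = 0; s < 3; ++s) {
              double x = 0.0;
              for (int q = 0; q < 3; ++q) x += l[q] * corn[tets[p][q + 1]][s];
              int base = (s == 0) ? i : (s == 1) ? j : k;
              pts[e][s] = origin[s] + dx * (base + x);
            }
          }
          double dd = 0;
          for (int s = 0; s < 3; ++s) {
            double q = pts[0][s] - pts[1][s]; dd += q * q;
          }
          if (dd < 1e-16) continue;
          for (int e = 0; e < 2; ++e)
            for (int s = 0; s < 3; ++s) segs.push_back(pts[e][s]);
        }
      }

  const int ns = segs.size() / 6;
  NumericMatrix out(ns, 6);
  for (int r = 0; r < ns; ++r)
    for (int c = 0; c < 6; ++c) out(r, c) = segs[r * 6 + c];
  colnames(out) = CharacterVector::create("x1","y1","z1","x2","y2","z2");
  return out;
}

// 2D variant: intersection points of the two isolines on a single-layer
// sheet; each square is split into two triangles.
// [[Rcpp::export]]
NumericMatrix tips2d_cpp(NumericMatrix V, NumericMatrix O, double dx,
                         NumericVector origin, double viso, double oiso) {
  const int nx = V.nrow(), ny = V.ncol();
  std::vector<double> pts;
  const int TRI[2][3][2] = { { {0,0},{1,0},{1,1} }, { {0,0},{1,1},{0,1} } };
  for (int j = 0; j + 1 < ny; ++j)
    for (int i = 0; i + 1 < nx; ++i) {
      double cv[2][2], co[2][2];
      bool ok = true;
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b) {
          cv[a][b] = V(i + a, j + b) - viso;
          co[a][b] = O(i + a, j + b) - oiso;
          if (!std::isfinite(cv[a][b]) || !std::isfinite(co[a][b])) ok = false;
        }
      if (!ok) continue;
      for (int t = 0; t < 2; ++t) {
        double a0 = cv[TRI[t][0][0]][TRI[t][0][1]];
        double b0 = co[TRI[t][0][0]][TRI[t][0][1]];
        double gA[2], gB[2];
        for (int s = 0; s < 2; ++s) {
          gA[s] = cv[TRI[t][s + 1][0]][TRI[t][s + 1][1]] - a0;
          gB[s] = co[TRI[t][s + 1][0]][TRI[t][s + 1][1]] - b0;
        }
        double det = gA[0] * gB[1] - gA[1] * gB[0];
        if (std::fabs(det) < 1e-14) continue;
        double l1 = (-a0 * gB[1] + b0 * gA[1]) / det;
        double l2 = (-b0 * gA[0] + a0 * gB[0]) / det;
        if (l1 < -1e-9 || l2 < -1e-9 || l1 + l2 > 1 + 1e-9) continue;
        double px = TRI[t][0][0] + l1 * (TRI[t][1][0] - TRI[t][0][0])
                  + l2 * (TRI[t][2][0] - TRI[t][0][0]);
        double py = TRI[t][0][1] + l1 * (TRI[t][1][1] - TRI[t][0][1])
                  + l2 * (TRI[t][2][1] - TRI[t][0][1]);
        pts.push_back(origin[0] + dx * (i + px));
        pts.push_back(origin[1] + dx * (j + py));
      }
    }
  const int np = pts.size() / 2;
  NumericMatrix out(np, 2);
  for (int r = 0; r < np; ++r) {
    out(r, 0) = pts[2 * r];
    out(r, 1) = pts[2 * r + 1];
  }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}

// resting state of the published control model
// [[Rcpp::export]]
NumericVector crn_rest_state_cpp() {
  NumericVector s(NSTATE);
  s[S_V] = -81.18; s[S_m] = 2.908e-3; s[S_h] = 9.649e-1; s[S_j] = 9.775e-1;
  s[S_oa] = 3.043e-2; s[S_oi] = 9.992e-1; s[S_ua] = 4.966e-3;
  s[S_ui] = 9.986e-1; s[S_xr] = 3.296e-5; s[S_xs] = 1.869e-2;
  s[S_d] = 1.367e-4; s[S_f] = 9.996e-1; s[S_fca] = 7.755e-1;
  s[S_u] = 0.0; s[S_v] = 1.0; s[S_w] = 9.992e-1;
  s[S_Nai] = 11.17; s[S_Ki] = 139.0; s[S_Cai] = 1.013e-4;
  s[S_Caup] = 1.488; s[S_Carel] = 1.488;
  s.attr("names") = CharacterVector::create(
    "V","m","h","j","oa","oi","ua","ui","xr","xs","d","f","fCa","u","v","w",
    "Na_i","K_i","Ca_i","Ca_up","Ca_rel");
  return s;
}
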
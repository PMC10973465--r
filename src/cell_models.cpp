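// Ionic action-potential models.
//
// Two model families are provided:
//  * "vent": a ventricular-type iPS-CM model in the Paci human-iPS-CM
//    lineage, i.e. the standard human ventricular Hodgkin-Huxley current
//    formulations (INa, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK, IpCa,
//    background and SR fluxes) with a reduced IK1 and a spontaneous-beating
//    funny current. If uses a single-gate mouse-embryonic formulation.
//  * "yni": the Yanagihara-Noma-Irisawa sinoatrial node model (INa, Is,
//    IK, Ih, Il), used for pacemaker-like cells.
//
// Units: V in mV, time in ms, membrane currents in A/F (numerically equal
// to mV/ms), concentrations in mM. Every constant is supplied from the R
// side registry, so all values are config-overridable.

#include "cell_models.h"
#include <cmath>

using namespace Rcpp;

ParamBag make_bag(const NumericVector& par) {
  ParamBag pb;
  CharacterVector nm = par.names();
  for (int i = 0; i < par.size(); ++i)
    pb.p[std::string(nm[i])] = par[i];
  return pb;
}

int model_n_state(int model) {
  return model == MODEL_VENT ? 18 : 7;
}

// ---------------------------------------------------------------- ventricular

VentConst make_vent_const(const ParamBag& pb) {
  VentConst c;
  const double TK = pb.get("T_degC") + 273.15;
  const double Tref = pb.get("Tref_degC") + 273.15;
  c.TK = TK;
  c.rtf = 8314.472 * TK / 96485.3415; // mV
  c.fgate = std::pow(pb.get("q10_gate"), (TK - Tref) / 10.0);
  c.fpump = std::pow(pb.get("q10_pump"), (TK - Tref) / 10.0);
  const double fcond = std::pow(pb.get("q10_cond"), (TK - Tref) / 10.0);
  c.gNa   = fcond * pb.get("gNa")  * pb.get("sNa");
  c.gCaL  = fcond * pb.get("gCaL") * pb.get("sCaL");
  c.gto   = fcond * pb.get("gto")  * pb.get("sto");
  c.gKr   = fcond * pb.get("gKr")  * pb.get("sKr");
  c.gKs   = fcond * pb.get("gKs")  * pb.get("sKs");
  c.gK1   = fcond * pb.get("gK1")  * pb.get("sK1");
  c.gf    = fcond * pb.get("gf")   * pb.get("sf");
  c.kNaCa = c.fpump * pb.get("kNaCa") * pb.get("sNaCa");
  c.PNaK  = c.fpump * pb.get("PNaK")  * pb.get("sNaK");
  c.gpCa  = c.fpump * pb.get("gpCa");
  c.gbNa  = fcond * pb.get("gbNa");
  c.gbCa  = fcond * pb.get("gbCa");
  c.Nao = pb.get("Nao"); c.Cao = pb.get("Cao"); c.Ko = pb.get("Ko");
  c.Ef = pb.get("Ef"); c.EfK_frac = pb.get("If_K_frac");
  c.CmF = pb.get("Cm_pF") * 1e-12;          // F
  c.VcL = pb.get("Vc_um3") * 1e-15;         // litres
  c.VsrL = pb.get("Vsr_um3") * 1e-15;
  c.Vmaxup = pb.get("Vmaxup"); c.Kup = pb.get("Kup");
  c.Vleak = pb.get("Vleak");
  c.arel = pb.get("arel"); c.brel = pb.get("brel"); c.crel = pb.get("crel");
  c.Bufc = pb.get("Bufc"); c.Kbufc = pb.get("Kbufc");
  c.Bufsr = pb.get("Bufsr"); c.Kbufsr = pb.get("Kbufsr");
  c.tau_min = pb.get("tau_min_ms");
  return c;
}

// State layout (18):
// 0 V, 1 m, 2 h, 3 j, 4 d, 5 f, 6 fCa, 7 r, 8 s, 9 xr1, 10 xr2, 11 xs,
// 12 y (If), 13 g (SR release), 14 Nai, 15 Cai, 16 CaSR, 17 Ki
void vent_rhs(const double* y, double* dy, const VentConst& c) {
  const double V = y[0];
  const double m = y[1], h = y[2], j = y[3];
  const double d = y[4], f = y[5], fCa = y[6];
  const double r = y[7], s = y[8];
  const double xr1 = y[9], xr2 = y[10], xs = y[11];
  const double yf = y[12], g = y[13];
  const double Nai = y[14], Cai = y[15], CaSR = y[16], Ki = y[17];

  const double rtf = c.rtf;
  const double ENa = rtf * std::log(c.Nao / Nai);
  const double EK  = rtf * std::log(c.Ko / Ki);
  const double EKs = rtf * std::log((c.Ko + 0.03 * c.Nao) / (Ki + 0.03 * Nai));
  const double ECa = 0.5 * rtf * std::log(c.Cao / Cai);

  // INa
  const double INa = c.gNa * m * m * m * h * j * (V - ENa);
  const double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                    0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  // floor on gate time constants keeps the explicit-Euler update stable at
  // dt = 0.01 ms where tau_m collapses below dt near rest; m_inf ~ 0 there,
  // so the floor has no dynamical effect (config: tau_min_ms)
  const double taum = std::max(c.tau_min, am * bm);
  const double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  const double tauh = 1.0 / (ah + bh);
  const double jinf = hinf;
  const double tauj = 1.0 / (aj + bj);

  // ICaL (Goldman-Hodgkin-Katz driving term)
  const double vfrt = V / rtf;
  const double Fc0 = 96485.3415;
  double dterm;
  if (std::fabs(vfrt) < 1e-6) {
    dterm = 2.0 * Fc0 * (Cai - 0.341 * c.Cao); // V -> 0 removable limit
  } else {
    const double e2 = std::exp(2.0 * vfrt);
    dterm = 4.0 * (V * Fc0 / rtf) * (Cai * e2 - 0.341 * c.Cao) / (e2 - 1.0);
  }
  const double ICaL = c.gCaL * d * f * fCa * dterm;
  const double dinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
  const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  const double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  const double taud = ad * bd + gd;
  const double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  const double tauf = 1125.0 * std::exp(-std::pow(V + 27.0, 2.0) / 240.0) + 80.0 +
                      165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  const double afca = 1.0 / (1.0 + std::pow(Cai / 0.000325, 8.0));
  const double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
  const double gfca = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
  const double fcainf = std::min(1.0, (afca + bfca + gfca + 0.23) / 1.46);
  const double taufca = 2.0;

  // Ito
  const double Ito = c.gto * r * s * (V - EK);
  const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  const double taur = 9.5 * std::exp(-std::pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  const double sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  const double taus = 85.0 * std::exp(-std::pow(V + 45.0, 2.0) / 320.0) +
                      5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;

  // IKr
  const double IKr = c.gKr * std::sqrt(c.Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  const double tauxr1 = axr1 * bxr1;
  const double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  const double tauxr2 = axr2 * bxr2;

  // IKs
  const double IKs = c.gKs * xs * xs * (V - EKs);
  const double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  const double axs = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
  const double bxs = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
  const double tauxs = axs * bxs;

  // IK1 (inward rectifier, strongly reduced in iPS-CM)
  const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bk1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double xk1 = ak1 / (ak1 + bk1);
  const double IK1 = c.gK1 * std::sqrt(c.Ko / 5.4) * xk1 * (V - EK);

  // If: mouse-embryonic single-gate funny current, mixed Na/K reversal Ef
  const double If = c.gf * yf * (V - c.Ef);
  const double yinf = 1.0 / (1.0 + std::exp((V + 78.0) / 5.0));
  const double tauy = 250.0 / (1.0 + std::exp((V + 15.0) / 10.0)) + 50.0;

  // pumps / exchangers
  const double INaCa = c.kNaCa *
      (std::exp(0.35 * vfrt) * Nai * Nai * Nai * c.Cao -
       std::exp(-0.65 * vfrt) * c.Nao * c.Nao * c.Nao * Cai * 2.5) /
      ((std::pow(87.5, 3.0) + std::pow(c.Nao, 3.0)) * (1.38 + c.Cao) *
       (1.0 + 0.1 * std::exp(-0.65 * vfrt)));
  const double INaK = c.PNaK * c.Ko * Nai /
      ((c.Ko + 1.0) * (Nai + 40.0) *
       (1.0 + 0.1245 * std::exp(-0.1 * vfrt) + 0.0353 * std::exp(-vfrt)));
  const double IpCa = c.gpCa * Cai / (Cai + 0.0005);
  const double IbNa = c.gbNa * (V - ENa);
  const double IbCa = c.gbCa * (V - ECa);

  // SR fluxes (mM/ms)
  const double Iup = c.fpump * c.Vmaxup / (1.0 + c.Kup * c.Kup / (Cai * Cai));
  const double Ileak = c.fpump * c.Vleak * (CaSR - Cai);
  const double Irel = c.fpump *
      (c.arel * CaSR * CaSR / (c.brel * c.brel + CaSR * CaSR) + c.crel) * d * g;
  const double ginf = (Cai < 0.00035)
      ? 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0))
      : 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));

  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + If +
                      INaCa + INaK + IpCa + IbNa + IbCa;

  dy[0] = -Iion;
  const double fg = c.fgate;
  dy[1] = fg * (minf - m) / taum;
  dy[2] = fg * (hinf - h) / tauh;
  dy[3] = fg * (jinf - j) / tauj;
  dy[4] = fg * (dinf - d) / taud;
  dy[5] = fg * (finf - f) / tauf;
  // fCa and g carry a rectification rule: no change toward smaller
  // inactivation while depolarized
  double dfca = fg * (fcainf - fCa) / taufca;
  if (fcainf > fCa && V > -60.0) dfca = 0.0;
  dy[6] = dfca;
  dy[7] = fg * (rinf - r) / taur;
  dy[8] = fg * (sinf - s) / taus;
  dy[9]  = fg * (xr1inf - xr1) / tauxr1;
  dy[10] = fg * (xr2inf - xr2) / tauxr2;
  dy[11] = fg * (xsinf - xs) / tauxs;
  dy[12] = fg * (yinf - yf) / tauy;
  double dg = fg * (ginf - g) / 2.0;
  if (ginf > g && V > -60.0) dg = 0.0;
  dy[13] = dg;

  // ion concentrations; fluxes in mM/ms (A / (z F Vc) in mol/L/s == mM/ms)
  const double Fc = 96485.3415;
  const double cur2flux = c.CmF / (Fc * c.VcL); // (A/F) -> mM/ms for z=1
  const double IfNa = (1.0 - c.EfK_frac) * If;
  dy[14] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa + IfNa) * cur2flux;
  const double bufc = 1.0 / (1.0 + c.Bufc * c.Kbufc / std::pow(Cai + c.Kbufc, 2.0));
  dy[15] = bufc * (-(ICaL + IbCa + IpCa - 2.0 * INaCa) * cur2flux / 2.0 +
                   Ileak - Iup + Irel);
  const double bufsr = 1.0 / (1.0 + c.Bufsr * c.Kbufsr / std::pow(CaSR + c.Kbufsr, 2.0));
  dy[16] = bufsr * (c.VcL / c.VsrL) * (Iup - Irel - Ileak);
  const double IfK = c.EfK_frac * If;
  dy[17] = -(Ito + IKr + IKs + IK1 + IfK - 2.0 * INaK) * cur2flux;
}

// ---------------------------------------------------------------- YNI node

YniConst make_yni_const(const ParamBag& pb) {
  YniConst c;
  const double TK = pb.get("T_degC") + 273.15;
  const double Tref = pb.get("Tref_degC") + 273.15;
  c.fgate = std::pow(pb.get("q10_gate"), (TK - Tref) / 10.0);
  const double fcond = std::pow(pb.get("q10_cond"), (TK - Tref) / 10.0);
  c.gNa = fcond * pb.get("gNa") * pb.get("sNa");
  c.gs  = fcond * pb.get("gs")  * pb.get("ss");
  c.gK  = fcond * pb.get("gK")  * pb.get("sK");
  c.gh  = fcond * pb.get("gh")  * pb.get("sh");
  c.gl  = fcond * pb.get("gl")  * pb.get("sl");
  return c;
}

static inline double safe_exp_frac(double num, double den) {
  // num/(exp-form den), guarding 0/0 removable singularities
  return num / den;
}

// State layout (7): 0 V, 1 m, 2 h, 3 d, 4 f, 5 p, 6 q
void yni_rhs(const double* y, double* dy, const YniConst& c) {
  const double V = y[0];
  const double m = y[1], h = y[2], d = y[3], f = y[4], p = y[5], q = y[6];

  // slow inward current
  const double Is = c.gs * (0.95 * d + 0.05) * (0.95 * f + 0.05) *
                    (std::exp((V - 30.0) / 15.0) - 1.0);
  const double ad = 1.045e-2 * ratexp1m(V + 35.0, 2.5) +
                    3.125e-2 * ratexp1m(V, 4.8);
  const double bd = 4.21e-3 * ratexp(V - 5.0, 2.5);
  const double af = 3.55e-4 * ratexp(V + 20.0, 5.633);
  const double bf = 9.44e-4 * (V + 60.0) / (1.0 + std::exp(-(V + 29.5) / 4.16));

  // delayed rectifier
  const double IK = c.gK * p * (std::exp(0.0277 * (V + 90.0)) - 1.0) /
                    std::exp(0.0277 * (V + 40.0));
  const double ap = 9e-3 / (1.0 + std::exp(-(V + 3.8) / 9.71)) + 6e-4;
  const double bp = 2.25e-4 * ratexp(V + 40.0, 13.3);

  // hyperpolarization-activated current
  const double Ih = c.gh * q * (V + 45.0);
  const double aq = 3.4e-4 * ratexp(V + 100.0, 4.4) + 4.95e-5;
  const double bq = 5e-4 * ratexp1m(V + 40.0, 6.0) + 8.45e-5;

  // fast sodium
  const double INa = c.gNa * m * m * m * h * (V - 30.0);
  const double am = ratexp1m(V + 37.0, 10.0);
  const double bm = 40.0 * std::exp(-0.056 * (V + 62.0));
  const double ah = 1.209e-3 * std::exp(-(V + 20.0) / 6.534);
  const double bh = 1.0 / (std::exp(-(V + 30.0) / 10.0) + 1.0);

  // leak
  const double Il = c.gl * (1.0 - std::exp(-(V + 60.0) / 20.0));

  dy[0] = -(INa + IK + Ih + Is + Il);
  const double fg = c.fgate;
  dy[1] = fg * (am * (1.0 - m) - bm * m);
  dy[2] = fg * (ah * (1.0 - h) - bh * h);
  dy[3] = fg * (ad * (1.0 - d) - bd * d);
  dy[4] = fg * (af * (1.0 - f) - bf * f);
  dy[5] = fg * (ap * (1.0 - p) - bp * p);
  dy[6] = fg * (aq * (1.0 - q) - bq * q);
}

void cell_rhs(int model, const double* y, double* dy, const ParamBag& pb) {
  if (model == MODEL_VENT) {
    VentConst c = make_vent_const(pb);
    vent_rhs(y, dy, c);
  } else {
    YniConst c = make_yni_const(pb);
    yni_rhs(y, dy, c);
  }
}

void default_init_state(int model, double* y) {
  if (model == MODEL_VENT) {
    y[0] = -70.0; y[1] = 0.0; y[2] = 0.75; y[3] = 0.75;
    y[4] = 0.0;  y[5] = 1.0;  y[6] = 1.0;  y[7] = 0.0; y[8] = 1.0;
    y[9] = 0.0;  y[10] = 1.0; y[11] = 0.0; y[12] = 0.1; y[13] = 1.0;
    y[14] = 10.0; y[15] = 0.0002; y[16] = 0.3; y[17] = 150.0;
  } else {
    y[0] = -60.0; y[1] = 0.1; y[2] = 0.9; y[3] = 0.01; y[4] = 0.9;
    y[5] = 0.2; y[6] = 0.05;
  }
}

// ----------------------------------------------------------------- wrappers

// [[Rcpp::export]]
NumericVector cpp_cell_derivs(int model, NumericVector state, NumericVector par) {
  ParamBag pb = make_bag(par);
  const int n = model_n_state(model);
  if (state.size() != n) stop("state has wrong length");
  NumericVector out(n);
  cell_rhs(model, REAL(state), REAL(out), pb);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_default_state(int model) {
  const int n = model_n_state(model);
  NumericVector out(n);
  default_init_state(model, REAL(out));
  return out;
}

// Forward-Euler integration of a single cell. fixed_idx: 1-based indices of
// state variables held constant (e.g. Ki, CaSR during GA evaluation).
// Records V every `stride_ms`. Returns list(time_ms, V_mV, state, n_steps).
// [[Rcpp::export]]
List cpp_simulate_cell(int model, NumericVector par, NumericVector state0,
                       double duration_ms, double dt_ms, double stride_ms,
                       IntegerVector fixed_idx, bool record_state = false) {
  ParamBag pb = make_bag(par);
  const int n = model_n_state(model);
  if (state0.size() != n) stop("state0 has wrong length");
  std::vector<double> y(REAL(state0), REAL(state0) + n), dy(n);
  std::vector<bool> fixed(n, false);
  for (int i = 0; i < fixed_idx.size(); ++i) {
    int k = fixed_idx[i] - 1;
    if (k < 0 || k >= n) stop("fixed_idx out of range");
    fixed[k] = true;
  }
  const long nsteps = (long)std::llround(duration_ms / dt_ms);
  const long rec_every = std::max(1L, (long)std::llround(stride_ms / dt_ms));
  const long nrec = nsteps / rec_every + 1;
  NumericVector tout(nrec), vout(nrec);
  NumericMatrix sout(record_state ? nrec : 0, record_state ? n : 0);

  VentConst vc; YniConst yc;
  if (model == MODEL_VENT) vc = make_vent_const(pb); else yc = make_yni_const(pb);

  long irec = 0;
  tout[irec] = 0.0; vout[irec] = y[0];
  if (record_state) for (int k = 0; k < n; ++k) sout(irec, k) = y[k];
  ++irec;
  for (long step = 1; step <= nsteps; ++step) {
    if (model == MODEL_VENT) vent_rhs(y.data(), dy.data(), vc);
    else yni_rhs(y.data(), dy.data(), yc);
    for (int k = 0; k < n; ++k) {
      if (fixed[k]) continue;
      y[k] += dt_ms * dy[k];
    }
    if (!std::isfinite(y[0])) {
      stop("integration diverged (non-finite membrane potential) at t = %f ms",
           step * dt_ms);
    }
    if (step % rec_every == 0 && irec < nrec) {
      tout[irec] = step * dt_ms;
      vout[irec] = y[0];
      if (record_state) for (int k = 0; k < n; ++k) sout(irec, k) = y[k];
      ++irec;
    }
  }
  return List::create(_["time_ms"] = tout, _["V_mV"] = vout,
                      _["state"] = NumericVector(y.begin(), y.end()),
                      _["states"] = sout,
                      _["n_steps"] = (double)nsteps);
}
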
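// 2D monodomain sheet solver.
//
//   dV/dt = -I_ion/C_m + (1/(rho_x S_x C_m)) d2V/dx2 + (1/(rho_y S_y C_m)) d2V/dy2
//
// Operator splitting per time step (Godunov): explicit forward-Euler ionic
// update per unit, then a Crank-Nicolson diffusion step realized as a
// Peaceman-Rachford ADI sweep (tridiagonal solves along x then y) with
// zero-flux Neumann boundaries. Voltage-dependent gate kinetics are
// tabulated on a fine V grid for speed; currents are evaluated exactly.
//
// Link currents between adjacent units are I = dV / R_link and can either be
// recorded or projected online onto precomputed magnetometer weights
// (B_axis(t) = sum_links w[axis,link] * I_link(t)), which keeps long
// simulations in O(1) memory with respect to link count.

#include "cell_models.h"
#include <cmath>
#include <climits>
#include <vector>

using namespace Rcpp;

// ------------------------------------------------------------- gate tables

struct GateTab {
  double v0, dv_inv;
  int n;
  // rows: per gate, columns: V samples; stores inf and tau (or alpha/beta)
  std::vector<std::vector<double>> inf, tau;
  int ngate;
};

static inline double lin(const std::vector<double>& t, double u, double v0,
                         double dv_inv, int n) {
  double x = (u - v0) * dv_inv;
  if (x <= 0) return t[0];
  if (x >= n - 1) return t[n - 1];
  int i = (int)x;
  double f = x - i;
  return t[i] * (1 - f) + t[i + 1] * f;
}

// ventricular gates in pool order (V excluded):
// 0 m, 1 h, 2 j, 3 d, 4 f, 5 (fCa: Cai dep), 6 r, 7 s, 8 xr1, 9 xr2,
// 10 xs, 11 y, 12 (g: Cai dep), 13 Nai, 14 Cai, 15 CaSR, 16 Ki
static const int VENT_VGATES = 11; // m h j d f r s xr1 xr2 xs y

static GateTab build_vent_tab(const VentConst& c) {
  GateTab T;
  T.v0 = -150.0; T.n = 4601; T.dv_inv = 1.0 / 0.05;
  T.ngate = VENT_VGATES;
  T.inf.assign(T.ngate, std::vector<double>(T.n));
  T.tau.assign(T.ngate, std::vector<double>(T.n));
  std::vector<double> y(18, 0.0), dy(18);
  for (int i = 0; i < T.n; ++i) {
    const double V = T.v0 + i * 0.05;
    // reuse the scalar RHS formulas by direct transcription
    const double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
    const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                      0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
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
    const double tauh = std::max(c.tau_min, 1.0 / (ah + bh));
    const double tauj = std::max(c.tau_min, 1.0 / (aj + bj));
    const double dinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    const double taud = std::max(c.tau_min, ad * bd + gd);
    const double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    const double tauf = 1125.0 * std::exp(-std::pow(V + 27.0, 2.0) / 240.0) +
                        80.0 + 165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
    const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    const double taur = 9.5 * std::exp(-std::pow(V + 40.0, 2.0) / 1800.0) + 0.8;
    const double sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    const double taus = 85.0 * std::exp(-std::pow(V + 45.0, 2.0) / 320.0) +
                        5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    const double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    const double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    const double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    const double axs = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
    const double yinf = 1.0 / (1.0 + std::exp((V + 78.0) / 5.0));
    const double tauy = 250.0 / (1.0 + std::exp((V + 15.0) / 10.0)) + 50.0;
    const double infs[VENT_VGATES] = {minf, hinf, hinf, dinf, finf, rinf,
                                      sinf, xr1inf, xr2inf, xsinf, yinf};
    const double taus_[VENT_VGATES] = {taum, tauh, tauj, taud, tauf, taur,
                                       taus, std::max(c.tau_min, axr1 * bxr1),
                                       std::max(c.tau_min, axr2 * bxr2),
                                       std::max(c.tau_min, axs * bxs), tauy};
    for (int g = 0; g < VENT_VGATES; ++g) {
      T.inf[g][i] = infs[g];
      T.tau[g][i] = taus_[g];
    }
  }
  return T;
}

// YNI gates: 0 m, 1 h, 2 d, 3 f, 4 p, 5 q (alpha in inf, beta in tau)
static const int YNI_GATES = 6;
static GateTab build_yni_tab(const YniConst&) {
  GateTab T;
  T.v0 = -150.0; T.n = 4601; T.dv_inv = 1.0 / 0.05;
  T.ngate = YNI_GATES;
  T.inf.assign(T.ngate, std::vector<double>(T.n));
  T.tau.assign(T.ngate, std::vector<double>(T.n));
  for (int i = 0; i < T.n; ++i) {
    const double V = T.v0 + i * 0.05;
    const double am = ratexp1m(V + 37.0, 10.0);
    const double bm = 40.0 * std::exp(-0.056 * (V + 62.0));
    const double ah = 1.209e-3 * std::exp(-(V + 20.0) / 6.534);
    const double bh = 1.0 / (std::exp(-(V + 30.0) / 10.0) + 1.0);
    const double ad = 1.045e-2 * ratexp1m(V + 35.0, 2.5) +
                      3.125e-2 * ratexp1m(V, 4.8);
    const double bd = 4.21e-3 * ratexp(V - 5.0, 2.5);
    const double af = 3.55e-4 * ratexp(V + 20.0, 5.633);
    const double bf = 9.44e-4 * (V + 60.0) / (1.0 + std::exp(-(V + 29.5) / 4.16));
    const double ap = 9e-3 / (1.0 + std::exp(-(V + 3.8) / 9.71)) + 6e-4;
    const double bp = 2.25e-4 * ratexp(V + 40.0, 13.3);
    const double aq = 3.4e-4 * ratexp(V + 100.0, 4.4) + 4.95e-5;
    const double bq = 5e-4 * ratexp1m(V + 40.0, 6.0) + 8.45e-5;
    const double as[YNI_GATES] = {am, ah, ad, af, ap, aq};
    const double bs[YNI_GATES] = {bm, bh, bd, bf, bp, bq};
    for (int g = 0; g < YNI_GATES; ++g) {
      T.inf[g][i] = as[g];
      T.tau[g][i] = bs[g];
    }
  }
  return T;
}

// -------------------------------------------------- per-unit ionic updates

// pool layout for ventricular units (17 entries, V lives in the field):
// 0..10 V-gates (m h j d f r s xr1 xr2 xs y), 11 fCa, 12 g,
// 13 Nai, 14 Cai, 15 CaSR, 16 Ki
static inline double vent_unit_step(double V, double* s, const VentConst& c,
                                    const GateTab& T, double dt) {
  const double rtf = c.rtf;
  const double Nai = s[13], Cai = s[14], CaSR = s[15], Ki = s[16];
  const double ENa = rtf * std::log(c.Nao / Nai);
  const double EK = rtf * std::log(c.Ko / Ki);
  const double EKs = rtf * std::log((c.Ko + 0.03 * c.Nao) / (Ki + 0.03 * Nai));
  const double ECa = 0.5 * rtf * std::log(c.Cao / Cai);
  const double m = s[0], h = s[1], j = s[2], d = s[3], f = s[4];
  const double r = s[5], sg = s[6], xr1 = s[7], xr2 = s[8], xs = s[9], yf = s[10];
  const double fCa = s[11], g = s[12];

  const double INa = c.gNa * m * m * m * h * j * (V - ENa);
  const double vfrt = V / rtf;
  const double Fc0 = 96485.3415;
  double dterm;
  if (std::fabs(vfrt) < 1e-6) {
    dterm = 2.0 * Fc0 * (Cai - 0.341 * c.Cao);
  } else {
    const double e2 = std::exp(2.0 * vfrt);
    dterm = 4.0 * (V * Fc0 / rtf) * (Cai * e2 - 0.341 * c.Cao) / (e2 - 1.0);
  }
  const double ICaL = c.gCaL * d * f * fCa * dterm;
  const double Ito = c.gto * r * sg * (V - EK);
  const double IKr = c.gKr * std::sqrt(c.Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double IKs = c.gKs * xs * xs * (V - EKs);
  const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bk1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = c.gK1 * std::sqrt(c.Ko / 5.4) * ak1 / (ak1 + bk1) * (V - EK);
  const double If = c.gf * yf * (V - c.Ef);
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
  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + If + INaCa + INaK +
                      IpCa + IbNa + IbCa;

  // gates via tables
  for (int gidx = 0; gidx < VENT_VGATES; ++gidx) {
    const double inf = lin(T.inf[gidx], V, T.v0, T.dv_inv, T.n);
    const double tau = lin(T.tau[gidx], V, T.v0, T.dv_inv, T.n);
    s[gidx] += dt * c.fgate * (inf - s[gidx]) / tau;
  }
  // Ca-dependent gates
  const double afca = 1.0 / (1.0 + std::pow(Cai / 0.000325, 8.0));
  const double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
  const double gfca = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
  const double fcainf = std::min(1.0, (afca + bfca + gfca + 0.23) / 1.46);
  if (!(fcainf > fCa && V > -60.0))
    s[11] += dt * c.fgate * (fcainf - fCa) / 2.0;
  const double ginf = (Cai < 0.00035)
      ? 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0))
      : 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));
  if (!(ginf > g && V > -60.0))
    s[12] += dt * c.fgate * (ginf - g) / 2.0;

  const double Iup = c.fpump * c.Vmaxup / (1.0 + c.Kup * c.Kup / (Cai * Cai));
  const double Ileak = c.fpump * c.Vleak * (CaSR - Cai);
  const double Irel = c.fpump *
      (c.arel * CaSR * CaSR / (c.brel * c.brel + CaSR * CaSR) + c.crel) * d * g;
  const double cur2flux = c.CmF / (Fc0 * c.VcL);
  const double IfNa = (1.0 - c.EfK_frac) * If;
  s[13] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa + IfNa) * cur2flux);
  const double bufc =
      1.0 / (1.0 + c.Bufc * c.Kbufc / std::pow(Cai + c.Kbufc, 2.0));
  s[14] += dt * bufc * (-(ICaL + IbCa + IpCa - 2.0 * INaCa) * cur2flux / 2.0 +
                        Ileak - Iup + Irel);
  const double bufsr =
      1.0 / (1.0 + c.Bufsr * c.Kbufsr / std::pow(CaSR + c.Kbufsr, 2.0));
  s[15] += dt * bufsr * (c.VcL / c.VsrL) * (Iup - Irel - Ileak);
  const double IfK = c.EfK_frac * If;
  s[16] += dt * (-(Ito + IKr + IKs + IK1 + IfK - 2.0 * INaK) * cur2flux);

  return Iion; // A/F
}

// pool layout for pacemaker units (6): 0 m, 1 h, 2 d, 3 f, 4 p, 5 q
static inline double yni_unit_step(double V, double* s, const YniConst& c,
                                   const GateTab& T, double dt) {
  const double m = s[0], h = s[1], d = s[2], f = s[3], p = s[4], q = s[5];
  const double Is = c.gs * (0.95 * d + 0.05) * (0.95 * f + 0.05) *
                    (std::exp((V - 30.0) / 15.0) - 1.0);
  const double IK = c.gK * p * (std::exp(0.0277 * (V + 90.0)) - 1.0) /
                    std::exp(0.0277 * (V + 40.0));
  const double Ih = c.gh * q * (V + 45.0);
  const double INa = c.gNa * m * m * m * h * (V - 30.0);
  const double Il = c.gl * (1.0 - std::exp(-(V + 60.0) / 20.0));
  for (int gidx = 0; gidx < YNI_GATES; ++gidx) {
    const double a = lin(T.inf[gidx], V, T.v0, T.dv_inv, T.n);
    const double b = lin(T.tau[gidx], V, T.v0, T.dv_inv, T.n);
    s[gidx] += dt * c.fgate * (a * (1.0 - s[gidx]) - b * s[gidx]);
  }
  return INa + IK + Ih + Is + Il;
}

// ------------------------------------------------------------ ADI helpers

// Thomas solve of (1 + a*L) v = rhs along a line with Neumann ends, where
// L is the negative 1D Laplacian stencil: row interior (-a, 1+2a, -a),
// boundary (1+a, -a).
static void tridiag_neumann(std::vector<double>& d, std::vector<double>& rhs,
                            double a, int n, std::vector<double>& cw) {
  // build and solve in place; cw: scratch for modified upper diag
  if (n == 1) { rhs[0] = rhs[0]; return; }
  // forward sweep
  double b0 = 1.0 + a;
  cw[0] = -a / b0;
  rhs[0] = rhs[0] / b0;
  for (int i = 1; i < n; ++i) {
    const double bi = (i == n - 1) ? (1.0 + a) : (1.0 + 2.0 * a);
    const double m = 1.0 / (bi + a * cw[i - 1]);
    cw[i] = -a * m;
    rhs[i] = (rhs[i] + a * rhs[i - 1]) * m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cw[i] * rhs[i + 1];
  (void)d;
}

// explicit Neumann Laplacian applied along one direction
static inline double lap_line(const double* v, int i, int n, int stride) {
  const double vm = (i > 0) ? v[-stride] : v[0];
  const double vp = (i < n - 1) ? v[stride] : v[0];
  return vm - 2.0 * v[0] + vp;
}

// ------------------------------------------------------------- main entry

// Pure diffusion (passive membrane, I_ion = 0) over n steps; exposes the
// ADI Crank-Nicolson core for verification against closed forms.
// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector Vin, int nx, int ny, double dt_ms,
                          double Dx, double Dy, int nsteps) {
  if (Vin.size() != nx * ny) stop("field size mismatch");
  std::vector<double> V(REAL(Vin), REAL(Vin) + Vin.size()), Vtmp(V.size());
  const double ax = 0.5 * dt_ms * Dx, ay = 0.5 * dt_ms * Dy;
  std::vector<double> line(std::max(nx, ny)), rhs(std::max(nx, ny)),
      cw(std::max(nx, ny));
  for (int step = 0; step < nsteps; ++step) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int k = j * nx + i;
        rhs[i] = V[k] + ay * lap_line(&V[k], j, ny, nx);
      }
      tridiag_neumann(line, rhs, ax, nx, cw);
      for (int i = 0; i < nx; ++i) Vtmp[j * nx + i] = rhs[i];
    }
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        const int k = j * nx + i;
        rhs[j] = Vtmp[k] + ax * lap_line(&Vtmp[k], i, nx, 1);
      }
      tridiag_neumann(line, rhs, ay, ny, cw);
      for (int j = 0; j < ny; ++j) V[j * nx + i] = rhs[j];
    }
  }
  return NumericVector(V.begin(), V.end());
}

// type: length nx*ny, 0 ventricular / 1 pacemaker, index k = j*nx + i.
// Dx, Dy: diffusion coefficients on the grid in 1/ms units (already divided
// by dx^2). wx, wy: optional weight matrices (n_axes x n_links) projecting
// link currents (A) onto recorded field channels.
// [[Rcpp::export]]
List cpp_simulate_tissue(int nx, int ny, IntegerVector type,
                         NumericVector vent_par, NumericVector yni_par,
                         NumericMatrix vent_state0, NumericVector yni_state0,
                         IntegerVector vent_fixed_pool,
                         double duration_ms, double dt_ms,
                         double Dx, double Dy,
                         double Rlink_x, double Rlink_y,
                         double v_stride_ms, double i_stride_ms,
                         Nullable<NumericMatrix> wx_, Nullable<NumericMatrix> wy_,
                         bool record_links, bool record_v,
                         IntegerVector stim_idx, double stim_start_ms,
                         double stim_dur_ms, double stim_amp,
                         double act_threshold) {
  const int nun = nx * ny;
  if (type.size() != nun) stop("type map size mismatch");
  ParamBag vb = make_bag(vent_par), yb = make_bag(yni_par);
  VentConst vc = make_vent_const(vb);
  YniConst yc = make_yni_const(yb);
  GateTab vT = build_vent_tab(vc);
  GateTab yT = build_yni_tab(yc);

  // state pools
  const int NSV = 17, NSY = 6;
  std::vector<double> V(nun), pool(nun * NSV, 0.0);
  // vent_state0: column per unit? Accept a single 18-vector default: col 0.
  // Here: vent_state0 is 18 x 1 (shared initial state), yni_state0 length 7.
  if (vent_state0.nrow() != 18) stop("vent_state0 must have 18 rows");
  if (yni_state0.size() != 7) stop("yni_state0 must have length 7");
  for (int k = 0; k < nun; ++k) {
    if (type[k] == 0) {
      V[k] = vent_state0(0, 0);
      double* s = &pool[(size_t)k * NSV];
      // single-cell order: V m h j d f fCa r s xr1 xr2 xs y g Nai Cai CaSR Ki
      // pool order:          m h j d f r s xr1 xr2 xs y fCa g Nai Cai CaSR Ki
      static const int perm[17] = {1, 2, 3, 4, 5, 7, 8, 9, 10, 11, 12,
                                   6, 13, 14, 15, 16, 17};
      for (int q = 0; q < 17; ++q) s[q] = vent_state0(perm[q], 0);
    } else {
      V[k] = yni_state0[0];
      double* s = &pool[(size_t)k * NSV];
      for (int q = 0; q < NSY; ++q) s[q] = yni_state0[q + 1];
    }
  }

  const long nsteps = (long)std::llround(duration_ms / dt_ms);
  const long v_every = record_v
      ? std::max(1L, (long)std::llround(v_stride_ms / dt_ms)) : LONG_MAX;
  const long i_every = std::max(1L, (long)std::llround(i_stride_ms / dt_ms));
  const int nlx = (nx - 1) * ny, nly = nx * (ny - 1);

  NumericMatrix wx, wy;
  bool have_w = false;
  int n_axes = 0;
  if (wx_.isNotNull() && wy_.isNotNull()) {
    wx = NumericMatrix(wx_); wy = NumericMatrix(wy_);
    if (wx.ncol() != nlx || wy.ncol() != nly) stop("weight matrix size mismatch");
    if (wx.nrow() != wy.nrow()) stop("weight matrices must have equal rows");
    n_axes = wx.nrow();
    have_w = true;
  }

  const long n_irec = nsteps / i_every;
  const long n_vrec = record_v ? (nsteps / v_every + 1) : 0;
  NumericMatrix Bout(have_w ? n_irec : 0, n_axes);
  NumericVector t_i(n_irec);
  NumericMatrix Vsnap(n_vrec, record_v ? nun : 0);
  NumericVector t_v(n_vrec);
  NumericMatrix Ix_rec(record_links ? n_irec : 0, record_links ? nlx : 0);
  NumericMatrix Iy_rec(record_links ? n_irec : 0, record_links ? nly : 0);
  NumericVector act(nun, NA_REAL);

  const double ax = 0.5 * dt_ms * Dx, ay = 0.5 * dt_ms * Dy;
  std::vector<double> line(std::max(nx, ny)), rhs(std::max(nx, ny)),
      cw(std::max(nx, ny)), Vtmp(nun);

  const long stim0 = (long)std::llround(stim_start_ms / dt_ms);
  const long stim1 = stim0 + (long)std::llround(stim_dur_ms / dt_ms);

  long ivrec = 0, iirec = 0;
  if (record_v) {
    t_v[ivrec] = 0.0;
    for (int k = 0; k < nun; ++k) Vsnap(ivrec, k) = V[k];
    ++ivrec;
  }

  for (long step = 1; step <= nsteps; ++step) {
    // 1) ionic update (clamped pool entries restored afterwards)
    for (int k = 0; k < nun; ++k) {
      double* s = &pool[(size_t)k * NSV];
      double Iion;
      if (type[k] == 0) {
        double held[4];
        for (int fi = 0; fi < vent_fixed_pool.size(); ++fi)
          held[fi] = s[vent_fixed_pool[fi]];
        Iion = vent_unit_step(V[k], s, vc, vT, dt_ms);
        for (int fi = 0; fi < vent_fixed_pool.size(); ++fi)
          s[vent_fixed_pool[fi]] = held[fi];
      } else {
        Iion = yni_unit_step(V[k], s, yc, yT, dt_ms);
      }
      V[k] += dt_ms * (-Iion);
    }
    if (step > stim0 && step <= stim1) {
      for (int si = 0; si < stim_idx.size(); ++si)
        V[stim_idx[si]] += dt_ms * stim_amp;
    }

    // 2) ADI diffusion (Peaceman-Rachford): x implicit/y explicit then swap
    if (Dx > 0 || Dy > 0) {
      // sweep 1: for each row j, solve (1 - ax Lx) V* = V + ay Ly V
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int k = j * nx + i;
          const double ly = lap_line(&V[k], j, ny, nx);
          rhs[i] = V[k] + ay * ly;
        }
        tridiag_neumann(line, rhs, ax, nx, cw);
        for (int i = 0; i < nx; ++i) Vtmp[j * nx + i] = rhs[i];
      }
      // sweep 2: for each column i, solve (1 - ay Ly) V^{n+1} = V* + ax Lx V*
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) {
          const int k = j * nx + i;
          const double lx = lap_line(&Vtmp[k], i, nx, 1);
          rhs[j] = Vtmp[k] + ax * lx;
        }
        tridiag_neumann(line, rhs, ay, ny, cw);
        for (int j = 0; j < ny; ++j) V[j * nx + i] = rhs[j];
      }
    }

    if (!std::isfinite(V[0]) || !std::isfinite(V[nun / 2]))
      stop("tissue solver diverged at frame %ld (t = %f ms)", step,
           step * dt_ms);

    // activation times
    for (int k = 0; k < nun; ++k)
      if (ISNA(act[k]) && V[k] >= act_threshold) act[k] = step * dt_ms;

    // 3) link currents / field projection
    if (step % i_every == 0) {
      t_i[iirec] = step * dt_ms;
      if (have_w || record_links) {
        // x links: (i,j)-(i+1,j), index l = j*(nx-1)+i
        for (int j = 0; j < ny; ++j) {
          for (int i = 0; i < nx - 1; ++i) {
            const int k = j * nx + i, l = j * (nx - 1) + i;
            const double I = (V[k] - V[k + 1]) * 1e-3 / Rlink_x; // A
            if (record_links) Ix_rec(iirec, l) = I;
            if (have_w)
              for (int axn = 0; axn < n_axes; ++axn)
                Bout(iirec, axn) += wx(axn, l) * I;
          }
        }
        for (int j = 0; j < ny - 1; ++j) {
          for (int i = 0; i < nx; ++i) {
            const int k = j * nx + i, l = j * nx + i;
            const double I = (V[k] - V[k + nx]) * 1e-3 / Rlink_y;
            if (record_links) Iy_rec(iirec, l) = I;
            if (have_w)
              for (int axn = 0; axn < n_axes; ++axn)
                Bout(iirec, axn) += wy(axn, l) * I;
          }
        }
      }
      ++iirec;
    }
    if (record_v && step % v_every == 0 && ivrec < n_vrec) {
      t_v[ivrec] = step * dt_ms;
      for (int k = 0; k < nun; ++k) Vsnap(ivrec, k) = V[k];
      ++ivrec;
    }
  }

  return List::create(
      _["time_v_ms"] = t_v, _["V"] = Vsnap,
      _["time_i_ms"] = t_i, _["B"] = Bout,
      _["Ix"] = Ix_rec, _["Iy"] = Iy_rec,
      _["activation_ms"] = act,
      _["V_final"] = NumericVector(V.begin(), V.end()));
}
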
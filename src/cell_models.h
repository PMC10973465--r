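#ifndef CARDIOMAG_CELL_MODELS_H
#define CARDIOMAG_CELL_MODELS_H

#include <Rcpp.h>
#include <map>
#include <string>

// Parameter bag: named doubles copied once per simulation call.
struct ParamBag {
  std::map<std::string, double> p;
  double get(const char* k) const {
    auto it = p.find(k);
    if (it == p.end()) Rcpp::stop("missing model parameter '%s'", k);
    return it->second;
  }
};

ParamBag make_bag(const Rcpp::NumericVector& par);

// x / (exp(x/s) - 1), continuous at x = 0 (limit s)
inline double ratexp(double x, double s) {
  const double u = x / s;
  if (std::fabs(u) < 1e-8) return s * (1.0 - u / 2.0);
  return x / std::expm1(u);
}
// x / (1 - exp(-x/s)), continuous at x = 0 (limit s)
inline double ratexp1m(double x, double s) {
  const double u = x / s;
  if (std::fabs(u) < 1e-8) return s * (1.0 + u / 2.0);
  return x / (-std::expm1(-u));
}

// model ids
enum ModelId { MODEL_VENT = 0, MODEL_YNI = 1 };

int model_n_state(int model);

// Fill dy (length n_state) with derivatives at state y. Units: V mV, t ms,
// currents A/F (== mV/ms on membrane), concentrations mM.
void cell_rhs(int model, const double* y, double* dy, const ParamBag& pb);

// Pre-resolved constants (scalings/Q10 applied) for speed in tissue loops.
struct VentConst {
  double gNa, gCaL, gto, gKr, gKs, gK1, gf, kNaCa, PNaK, gpCa, gbNa, gbCa;
  double Nao, Cao, Ko, Ef, EfK_frac;
  double CmF, VcL, VsrL;
  double Vmaxup, Kup, Vleak, arel, brel, crel;
  double Bufc, Kbufc, Bufsr, Kbufsr;
  double tau_min;
  double TK, rtf;     // temperature (K), RT/F in mV
  double fgate, fpump; // Q10 factors
};
struct YniConst {
  double gNa, gs, gK, gh, gl;
  double fgate;
};

VentConst make_vent_const(const ParamBag& pb);
YniConst  make_yni_const(const ParamBag& pb);

void vent_rhs(const double* y, double* dy, const VentConst& c);
void yni_rhs(const double* y, double* dy, const YniConst& c);

void default_init_state(int model, double* y);

#endif
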
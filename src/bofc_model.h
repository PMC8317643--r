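#ifndef RESTFORGE_BOFC_MODEL_H
#define RESTFORGE_BOFC_MODEL_H

#include <Rcpp.h>
#include <cmath>

// Four-variable minimal ventricular model (fast inward, slow outward, slow
// inward currents; Heaviside-switched gate kinetics). Parameters are consumed
// positionally in the canonical 28-element order documented in bofc_params().
struct BofcPar {
  double uo, uu, thv, thw, thvm, tho;
  double tv1m, tv2m, tvp;
  double tw1m, tw2m, kwm, uwm, twp;
  double tfi, to1, to2;
  double tso1, tso2, kso, uso;
  double ts1, ts2, ks, us;
  double tsi, twinf, winfstar;
};

inline BofcPar as_bofc_par(const Rcpp::NumericVector& p) {
  if (p.size() != 28) Rcpp::stop("parameter vector must have 28 elements");
  BofcPar q;
  q.uo = p[0];  q.uu = p[1];  q.thv = p[2];  q.thw = p[3];  q.thvm = p[4];
  q.tho = p[5]; q.tv1m = p[6]; q.tv2m = p[7]; q.tvp = p[8];
  q.tw1m = p[9]; q.tw2m = p[10]; q.kwm = p[11]; q.uwm = p[12]; q.twp = p[13];
  q.tfi = p[14]; q.to1 = p[15]; q.to2 = p[16];
  q.tso1 = p[17]; q.tso2 = p[18]; q.kso = p[19]; q.uso = p[20];
  q.ts1 = p[21]; q.ts2 = p[22]; q.ks = p[23]; q.us = p[24];
  q.tsi = p[25]; q.twinf = p[26]; q.winfstar = p[27];
  return q;
}

// Heaviside with H(0) = 1 (switch engages at the threshold itself).
inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

// tanh with a saturation cutoff; |x| >= 20 rounds to +/-1 in double
// precision, so this is bit-identical to std::tanh while skipping the
// libm call for the (frequent) saturated gate arguments.
inline double tanh_sat(double x) {
  if (x >= 20.0) return 1.0;
  if (x <= -20.0) return -1.0;
  return std::tanh(x);
}

inline double bofc_s_inf(const BofcPar& p, double u) {
  return (1.0 + tanh_sat(p.ks * (u - p.us))) / 2.0;
}

// Rates of change and the three transmembrane currents at one state.
// du = -(jfi + jso + jsi) + istim.
inline void bofc_rates(const BofcPar& p,
                       double u, double v, double w, double s, double istim,
                       double& du, double& dv, double& dw, double& ds,
                       double& jfi, double& jso, double& jsi) {
  const double hv  = heav(u - p.thv);
  const double hw  = heav(u - p.thw);
  const double hvm = heav(u - p.thvm);
  const double ho  = heav(u - p.tho);

  const double tvm = (1.0 - hvm) * p.tv1m + hvm * p.tv2m;
  const double twm = p.tw1m +
    (p.tw2m - p.tw1m) * (1.0 + tanh_sat(p.kwm * (u - p.uwm))) / 2.0;
  const double tso = p.tso1 +
    (p.tso2 - p.tso1) * (1.0 + tanh_sat(p.kso * (u - p.uso))) / 2.0;
  const double ts = (1.0 - hw) * p.ts1 + hw * p.ts2;
  const double to = (1.0 - ho) * p.to1 + ho * p.to2;

  const double vinf = (u < p.thvm) ? 1.0 : 0.0;
  const double winf = (1.0 - ho) * (1.0 - u / p.twinf) + ho * p.winfstar;

  jfi = -v * hv * (u - p.thv) * (p.uu - u) / p.tfi;
  jso = (u - p.uo) * (1.0 - hw) / to + hw / tso;
  jsi = -hw * w * s / p.tsi;

  du = -(jfi + jso + jsi) + istim;
  dv = (1.0 - hv) * (vinf - v) / tvm - hv * v / p.tvp;
  dw = (1.0 - hw) * (winf - w) / twm - hw * w / p.twp;
  ds = (bofc_s_inf(p, u) - s) / ts;
}

#endif
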
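#include "bofc_model.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_bofc_rates(NumericVector params, NumericVector state, double istim) {
  BofcPar p = as_bofc_par(params);
  if (state.size() != 4) stop("state must have 4 elements (u, v, w, s)");
  for (int i = 0; i < 4; ++i)
    if (!R_finite(state[i])) stop("non-finite state variable");
  double du, dv, dw, ds, jfi, jso, jsi;
  bofc_rates(p, state[0], state[1], state[2], state[3], istim,
             du, dv, dw, ds, jfi, jso, jsi);
  return List::create(
    _["rates"] = NumericVector::create(_["u"] = du, _["v"] = dv,
                                       _["w"] = dw, _["s"] = ds),
    _["J_fi"] = jfi, _["J_so"] = jso, _["J_si"] = jsi);
}

// [[Rcpp::export]]
NumericVector cpp_rest_state(NumericVector params) {
  BofcPar p = as_bofc_par(params);
  return NumericVector::create(_["u"] = p.uo, _["v"] = 1.0, _["w"] = 1.0,
                               _["s"] = bofc_s_inf(p, p.uo));
}

struct BeatRow {
  double cl, beat, t_stim, t_act, dudt_max, u_base, u_max, apd90, t_repol, di;
  int captured;
};

struct ProtocolOut {
  std::vector<BeatRow> rows;
  std::vector<double> morph;
  double state[4];
  bool blown;
  double t_blow;
};

// Paced train across consecutive cycle-length blocks with state carried over.
// Per beat: activation (max du/dt), APD90 via linear interpolation at the
// 90%-repolarization level (last downward crossing before the next stimulus),
// and the diastolic interval from the previous beat's repolarization end.
static ProtocolOut run_protocol(const BofcPar& p, const double* state0,
                                const NumericVector& cls, int beats,
                                double dt, double stim_amp, double stim_dur,
                                double morph_cl) {
  ProtocolOut out;
  out.blown = false;
  out.t_blow = NA_REAL;
  double u = state0[0], v = state0[1], w = state0[2], s = state0[3];
  double t_global = 0.0;
  double prev_repol = NA_REAL;
  std::vector<double> buf;
  const double capture_amp = 0.3;  // u-units; full AP amplitude is ~1.6

  for (int b = 0; b < cls.size(); ++b) {
    const double cl = cls[b];
    const int nstep = (int)std::lround(cl / dt);
    buf.resize(nstep + 1);
    for (int k = 0; k < beats; ++k) {
      buf[0] = u;
      double dudt_max = R_NegInf, t_act_local = 0.0;
      for (int i = 0; i < nstep; ++i) {
        const double tl = i * dt;
        const double istim = (tl < stim_dur) ? stim_amp : 0.0;
        double du, dv, dw, ds, jfi, jso, jsi;
        bofc_rates(p, u, v, w, s, istim, du, dv, dw, ds, jfi, jso, jsi);
        if (du > dudt_max) { dudt_max = du; t_act_local = tl; }
        u += dt * du;
        v += dt * dv;
        w += dt * dw;
        s += dt * ds;
        buf[i + 1] = u;
        if (!R_finite(u) || std::fabs(u) > 20.0) {
          out.blown = true;
          out.t_blow = t_global + tl;
          out.state[0] = u; out.state[1] = v; out.state[2] = w; out.state[3] = s;
          return out;
        }
      }
      BeatRow r;
      r.cl = cl;
      r.beat = k + 1;
      r.t_stim = t_global;
      r.u_base = buf[0];
      double umax = R_NegInf;
      int ipk = 0;
      for (int i = 0; i <= nstep; ++i)
        if (buf[i] > umax) { umax = buf[i]; ipk = i; }
      r.u_max = umax;
      r.dudt_max = dudt_max;
      r.t_act = t_global + t_act_local;
      // an action potential requires a regenerative upstroke, not just the
      // stimulus deflection: amplitude above the capture floor AND a peak
      // beyond the fast-inward activation threshold
      r.captured = ((umax - r.u_base) > capture_amp &&
                    umax > p.thv + 0.05) ? 1 : 0;
      r.apd90 = NA_REAL;
      r.t_repol = NA_REAL;
      r.di = NA_REAL;
      if (r.captured) {
        const double thr = r.u_base + 0.1 * (umax - r.u_base);
        double t_cross = NA_REAL;
        for (int i = nstep - 1; i >= ipk; --i) {
          if (buf[i] >= thr && buf[i + 1] < thr) {
            const double frac = (buf[i] - thr) / (buf[i] - buf[i + 1]);
            t_cross = (i + frac) * dt;
            break;
          }
        }
        if (R_finite(t_cross)) {
          r.apd90 = t_cross - t_act_local;
          r.t_repol = t_global + t_cross;
        }
        if (R_finite(prev_repol)) r.di = r.t_act - prev_repol;
        prev_repol = r.t_repol;  // NA if this beat never repolarized
      } else {
        prev_repol = NA_REAL;
      }
      out.rows.push_back(r);

      if (morph_cl > 0 && std::fabs(cl - morph_cl) < 1e-9 && k == beats - 1) {
        const int stride = (int)std::lround(1.0 / dt);
        const int m = (int)std::floor(cl);
        out.morph.resize(m);
        for (int j = 0; j < m; ++j) out.morph[j] = buf[j * stride];
      }
      t_global += nstep * dt;
    }
  }
  out.state[0] = u; out.state[1] = v; out.state[2] = w; out.state[3] = s;
  return out;
}

static NumericMatrix rows_to_matrix(const std::vector<BeatRow>& rows) {
  NumericMatrix m(rows.size(), 11);
  colnames(m) = CharacterVector::create(
    "cl", "beat", "t_stim", "t_act", "dudt_max", "u_base", "u_max",
    "apd90", "t_repol", "di", "captured");
  for (size_t i = 0; i < rows.size(); ++i) {
    m(i, 0) = rows[i].cl;      m(i, 1) = rows[i].beat;
    m(i, 2) = rows[i].t_stim;  m(i, 3) = rows[i].t_act;
    m(i, 4) = rows[i].dudt_max; m(i, 5) = rows[i].u_base;
    m(i, 6) = rows[i].u_max;   m(i, 7) = rows[i].apd90;
    m(i, 8) = rows[i].t_repol; m(i, 9) = rows[i].di;
    m(i, 10) = rows[i].captured;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_protocol(NumericVector params, NumericVector state0, NumericVector cls,
                  int beats, double dt, double stim_amp, double stim_dur,
                  double morph_cl) {
  BofcPar p = as_bofc_par(params);
  double s0[4] = {state0[0], state0[1], state0[2], state0[3]};
  ProtocolOut out = run_protocol(p, s0, cls, beats, dt, stim_amp, stim_dur,
                                 morph_cl);
  return List::create(
    _["beats"] = rows_to_matrix(out.rows),
    _["morph"] = NumericVector(out.morph.begin(), out.morph.end()),
    _["state"] = NumericVector::create(_["u"] = out.state[0],
                                       _["v"] = out.state[1],
                                       _["w"] = out.state[2],
                                       _["s"] = out.state[3]),
    _["blown"] = out.blown, _["t_blow"] = out.t_blow);
}

// Full-resolution voltage trace for one or more cycle-length blocks.
// [[Rcpp::export]]
List cpp_simulate(NumericVector params, NumericVector state0, NumericVector cls,
                  int beats, double dt, double stim_amp, double stim_dur) {
  BofcPar p = as_bofc_par(params);
  double u = state0[0], v = state0[1], w = state0[2], s = state0[3];
  long total_steps = 0;
  for (int b = 0; b < cls.size(); ++b)
    total_steps += beats * (long)std::lround(cls[b] / dt);
  NumericVector uout(total_steps + 1);
  NumericVector stim_times(cls.size() * beats);
  uout[0] = u;
  long idx = 0;
  int sidx = 0;
  double t_global = 0.0;
  for (int b = 0; b < cls.size(); ++b) {
    const int nstep = (int)std::lround(cls[b] / dt);
    for (int k = 0; k < beats; ++k) {
      stim_times[sidx++] = t_global;
      for (int i = 0; i < nstep; ++i) {
        const double istim = (i * dt < stim_dur) ? stim_amp : 0.0;
        double du, dv, dw, ds, jfi, jso, jsi;
        bofc_rates(p, u, v, w, s, istim, du, dv, dw, ds, jfi, jso, jsi);
        u += dt * du;
        v += dt * dv;
        w += dt * dw;
        s += dt * ds;
        uout[++idx] = u;
        if (!R_finite(u) || std::fabs(u) > 20.0)
          stop("numerical blow-up at t = %f ms", t_global + i * dt);
      }
      t_global += nstep * dt;
    }
  }
  return List::create(
    _["u"] = uout, _["dt"] = dt, _["stim_times"] = stim_times,
    _["state"] = NumericVector::create(_["u"] = u, _["v"] = v,
                                       _["w"] = w, _["s"] = s));
}

// Mean absolute restitution error of a whole population against a target
// curve/point set, plus an optional morphology-template penalty. Returns one
// fitness value (ms) per row of parmat; failures map to `penalty`.
// [[Rcpp::export]]
NumericVector cpp_fitness_pop(NumericMatrix parmat, NumericVector cls,
                              int beats, double dt, double stim_amp,
                              double stim_dur, int drop_first, int drop_last,
                              int target_type, double alpha, double beta,
                              double di_lo, double di_hi,
                              NumericVector tdi, NumericVector tari,
                              NumericVector morph_template, double lambda,
                              double mv_scale, double penalty) {
  const int n = parmat.nrow();
  NumericVector fit(n);
  const double morph_cl = (lambda > 0 && morph_template.size() > 0) ? cls[0] : -1.0;
  for (int r = 0; r < n; ++r) {
    NumericVector pv = parmat(r, _);
    BofcPar p = as_bofc_par(pv);
    double s0[4] = {p.uo, 1.0, 1.0, bofc_s_inf(p, p.uo)};
    ProtocolOut out = run_protocol(p, s0, cls, beats, dt, stim_amp, stim_dur,
                                   morph_cl);
    if (out.blown) { fit[r] = penalty; continue; }
    double sum = 0.0;
    int nterm = 0;
    bool bad = false;
    for (size_t i = 0; i < out.rows.size(); ++i) {
      const BeatRow& b = out.rows[i];
      if (b.beat <= drop_first || b.beat > beats - drop_last) continue;
      if (!b.captured || !R_finite(b.apd90)) { bad = true; break; }
      if (!R_finite(b.di)) continue;  // first beat has no preceding DI
      if (b.di < di_lo || b.di > di_hi) continue;
      double tgt;
      if (target_type == 0) {
        tgt = alpha + beta * std::log(b.di);
      } else {
        // linear interpolation on (tdi, tari), tdi ascending
        if (b.di <= tdi[0]) continue;
        if (b.di >= tdi[tdi.size() - 1]) continue;
        int j = 0;
        while (j < tdi.size() - 2 && tdi[j + 1] < b.di) ++j;
        const double f = (b.di - tdi[j]) / (tdi[j + 1] - tdi[j]);
        tgt = tari[j] + f * (tari[j + 1] - tari[j]);
      }
      sum += std::fabs(b.apd90 - tgt);
      ++nterm;
    }
    if (bad || nterm == 0) { fit[r] = penalty; continue; }
    double f = sum / nterm;
    if (morph_cl > 0) {
      const size_t m = std::min(out.morph.size(),
                                (size_t)morph_template.size());
      if (m == 0) { fit[r] = penalty; continue; }
      double msum = 0.0;
      for (size_t j = 0; j < m; ++j)
        msum += std::fabs(out.morph[j] - morph_template[j]);
      f += lambda * mv_scale * msum / m;
    }
    fit[r] = f;
  }
  return fit;
}
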
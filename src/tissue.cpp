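#include "bofc_model.h"
using namespace Rcpp;

// Five-point Laplacian with no-flux (mirror) boundaries: absent neighbors
// contribute nothing, so the discrete operator sums to zero over the grid.
// [[Rcpp::export]]
NumericMatrix cpp_laplacian(NumericMatrix u, double dx) {
  const int nr = u.nrow(), nc = u.ncol();
  NumericMatrix lap(nr, nc);
  const double inv = 1.0 / (dx * dx);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double a = 0.0;
      if (i > 0)      a += u(i - 1, j) - u(i, j);
      if (i < nr - 1) a += u(i + 1, j) - u(i, j);
      if (j > 0)      a += u(i, j - 1) - u(i, j);
      if (j < nc - 1) a += u(i, j + 1) - u(i, j);
      lap(i, j) = a * inv;
    }
  }
  return lap;
}

// Explicit monodomain integration on an nx-by-ny sheet. Stimuli are
// rectangular node patches (stims rows: t_on, dur, amp, x0, x1, y0, y1;
// 0-based inclusive node ranges). Activation = upward crossing of act_thr
// with a per-node deadtime. Early exit when the sheet is quiescent after the
// last stimulus, or as soon as an activation later than sustain_t is seen.
// [[Rcpp::export]]
List cpp_tissue_run(NumericVector params, int nx, int ny, double dx, double dt,
                    double D, NumericVector state0, NumericMatrix stims,
                    double t_end, IntegerVector record_idx, double act_thr,
                    double act_deadtime, double t_mark, double quiet_u,
                    double quiet_after, double sustain_t) {
  BofcPar p = as_bofc_par(params);
  const int N = nx * ny;
  std::vector<double> u(N, state0[0]), v(N, state0[1]), w(N, state0[2]),
      s(N, state0[3]), unew(N);
  std::vector<double> last_act(N, R_NegInf);
  std::vector<double> first_act(N, NA_REAL);
  const int nstim = stims.nrow();
  std::vector<int> on_step(nstim);
  for (int k = 0; k < nstim; ++k)
    on_step[k] = (int)std::lround(stims(k, 0) / dt);
  const double r = dt * D / (dx * dx);
  const int nsteps = (int)std::lround(t_end / dt);
  const int nrec = record_idx.size();
  NumericMatrix traces(nrec > 0 ? nsteps + 1 : 0, nrec);
  for (int q = 0; q < nrec; ++q) traces(0, q) = u[record_idx[q]];

  double global_last_act = R_NegInf;
  long n_act = 0, n_act_post = 0;
  std::string stopped = "end";
  double t_stop = t_end;
  std::vector<int> active;

  int step = 0;
  for (; step < nsteps; ++step) {
    const double t = step * dt;
    active.clear();
    for (int k = 0; k < nstim; ++k)
      if (step >= on_step[k] && (step - on_step[k]) * dt < stims(k, 1))
        active.push_back(k);

    double umax = R_NegInf;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * y;
        const double ui = u[i];
        double istim = 0.0;
        for (size_t a = 0; a < active.size(); ++a) {
          const int k = active[a];
          if (x >= stims(k, 3) && x <= stims(k, 4) &&
              y >= stims(k, 5) && y <= stims(k, 6))
            istim += stims(k, 2);
        }
        double du, dv, dw, ds, jfi, jso, jsi;
        bofc_rates(p, ui, v[i], w[i], s[i], istim, du, dv, dw, ds, jfi, jso, jsi);
        double lap = 0.0;
        if (x > 0)      lap += u[i - 1] - ui;
        if (x < nx - 1) lap += u[i + 1] - ui;
        if (y > 0)      lap += u[i - nx] - ui;
        if (y < ny - 1) lap += u[i + nx] - ui;
        const double un = (ui + dt * du) + r * lap;
        unew[i] = un;
        v[i] += dt * dv;
        w[i] += dt * dw;
        s[i] += dt * ds;
        if (un > umax) umax = un;
        if (un >= act_thr && ui < act_thr) {
          const double tn = t + dt;
          if (tn - last_act[i] > act_deadtime) {
            last_act[i] = tn;
            if (tn > global_last_act) global_last_act = tn;
            ++n_act;
            if (tn >= t_mark) {
              ++n_act_post;
              if (!R_finite(first_act[i])) first_act[i] = tn;
            }
          }
        }
      }
    }
    if (!R_finite(umax) || umax > 20.0)
      stop("numerical blow-up at t = %f ms", t);
    std::swap(u, unew);
    for (int q = 0; q < nrec; ++q) traces(step + 1, q) = u[record_idx[q]];
    if (R_finite(sustain_t) && global_last_act > sustain_t) {
      stopped = "sustained";
      t_stop = (step + 1) * dt;
      break;
    }
    const double t_next = (step + 1) * dt;
    if (t_next > quiet_after && umax < quiet_u) {
      stopped = "quiet";
      t_stop = t_next;
      break;
    }
  }

  NumericMatrix fam(nx, ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) fam(x, y) = first_act[x + nx * y];
  List st = List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["s"] = NumericVector(s.begin(), s.end()));
  List res = List::create(
    _["last_activation"] = R_finite(global_last_act) ? global_last_act : NA_REAL,
    _["n_activations"] = (double)n_act,
    _["n_activations_post"] = (double)n_act_post,
    _["first_activation_map"] = fam,
    _["t_stop"] = t_stop, _["stopped"] = stopped,
    _["state"] = st);
  if (nrec > 0) {
    if (stopped != "end") {
      // truncate unwritten tail of the trace matrix
      const int used = (int)std::lround(t_stop / dt) + 1;
      NumericMatrix tr2(used, nrec);
      for (int q = 0; q < nrec; ++q)
        for (int i = 0; i < used; ++i) tr2(i, q) = traces(i, q);
      res["traces"] = tr2;
    } else {
      res["traces"] = traces;
    }
  }
  return res;
}
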
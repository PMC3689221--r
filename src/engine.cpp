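// Discrete-time simulation core: conductance decay, delayed spike delivery
// through a ring buffer, hybrid Euler integration of the neuron model,
// nearest-neighbour STDP processing on spikes, homeostatic drift, and
// recording. The scalar R implementation in R/reference_engine.R follows
// the same event ordering operation for operation; the two must produce
// identical spike streams under equal seeds.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clampw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

// piecewise-constant symmetric window: d_in inside the inner disc,
// d_out in the annulus [inner, outer], 0 outside
static inline double tophat_eval(double adt, double inner, double outer,
                                 double d_in, double d_out) {
  if (adt < inner) return d_in;
  if (adt >= inner && adt <= outer) return d_out;
  return 0.0;
}

// [[Rcpp::export]]
List engine_run_cpp(int N, IntegerVector roles,
                    NumericVector pa, NumericVector pb, NumericVector pc,
                    NumericVector pd, NumericVector pvr, NumericVector pvt,
                    NumericVector pvp, NumericVector pC, NumericVector pk,
                    IntegerVector pform,
                    NumericMatrix We, NumericMatrix Wi,
                    IntegerMatrix Ae, IntegerMatrix Ai,
                    IntegerMatrix DeS, IntegerMatrix DiS,
                    IntegerMatrix ruleE, IntegerMatrix ruleI,
                    List triplet, NumericMatrix ihwin,
                    double wmax_i,
                    NumericVector omegaD, double tau_omega,
                    double Ee, double Ei,
                    double dec_e, double dec_i1, double dec_i2,
                    IntegerVector ipool,
                    IntegerVector in_off, IntegerVector in_targets,
                    double in_w, int in_delay_steps,
                    IntegerVector pacing_delay_steps, double pacing_w,
                    IntegerVector ext_step, IntegerVector ext_id,
                    double dt, int n_total, double sigma,
                    int snap_period, bool record_spikes,
                    NumericVector v0, NumericVector u0, NumericVector s0) {
  const double tau_ltp = as<double>(triplet["tau_ltp_e"]);
  const double tau_ltd = as<double>(triplet["tau_ltd_e"]);
  const double dltp = as<double>(triplet["delta_ltp_e"]);
  const double dltd = as<double>(triplet["delta_ltd_e"]);
  const double wmin_e = as<double>(triplet["w_min_e"]);
  const double wmax_e = as<double>(triplet["w_max_e"]);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> s(s0.begin(), s0.end());
  std::vector<double> Ge(N, 0.0), Gi1(N, 0.0), Gi2(N, 0.0);
  std::vector<double> t_last(N, -1.0);
  std::vector<double> lastLTD((size_t)N * N, 0.0);
  std::vector<int> inS;

  // ring buffer of pending conductance increments
  int maxdel = in_delay_steps;
  for (int i = 0; i < N; ++i) {
    if (pacing_delay_steps[i] > maxdel) maxdel = pacing_delay_steps[i];
    for (int j = 0; j < N; ++j) {
      if (Ae(i, j) && DeS(i, j) > maxdel) maxdel = DeS(i, j);
      if (Ai(i, j) && DiS(i, j) > maxdel) maxdel = DiS(i, j);
    }
  }
  int L = maxdel + 2;
  std::vector<std::vector<double>> ringE(L, std::vector<double>(N, 0.0));
  std::vector<std::vector<double>> ringI1(L, std::vector<double>(N, 0.0));
  std::vector<std::vector<double>> ringI2(L, std::vector<double>(N, 0.0));

  std::vector<int> sp_step_out;
  std::vector<int> sp_id_out;
  List snaps;
  const double drift = (dt / 1000.0) / tau_omega;
  const double sdec = 1.0 / tau_omega;
  int ext_ptr = 0;
  const int n_ext = ext_step.size();
  RNGScope scope;

  for (int t = 0; t < n_total; ++t) {
    const double t_now = (t + 1) * dt;
    const int slot = t % L;
    // 1. decay pools, 2. apply deliveries due this step
    for (int i = 0; i < N; ++i) {
      Ge[i] = Ge[i] * dec_e + ringE[slot][i];
      Gi1[i] = Gi1[i] * dec_i1 + ringI1[slot][i];
      Gi2[i] = Gi2[i] * dec_i2 + ringI2[slot][i];
      ringE[slot][i] = 0.0;
      ringI1[slot][i] = 0.0;
      ringI2[slot][i] = 0.0;
    }
    // 3. enqueue external input events emitted at this step
    while (ext_ptr < n_ext && ext_step[ext_ptr] == t) {
      int id = ext_id[ext_ptr];
      if (id < 0) { // pacing: one delivery per recurrent target, fixed delay
        for (int r = 0; r < N; ++r) {
          int te = t + pacing_delay_steps[r];
          if (te < n_total) ringI1[te % L][r] += pacing_w;
        }
      } else {
        int te = t + in_delay_steps;
        if (te < n_total) {
          for (int q = in_off[id]; q < in_off[id + 1]; ++q) {
            ringE[te % L][in_targets[q]] += in_w;
          }
        }
      }
      ++ext_ptr;
    }
    // 4.-5. noise + integration; collect spikers
    inS.clear();
    for (int i = 0; i < N; ++i) {
      double In = (sigma > 0.0) ? R::rnorm(0.0, sigma) : 0.0;
      double vi = v[i], ui = u[i];
      double Isyn = s[i] * Ge[i] * (Ee - vi) + (Gi1[i] + Gi2[i]) * (Ei - vi);
      double dv, du;
      if (pform[i] == 0) {
        dv = (pk[i] * (vi - pvr[i]) * (vi - pvt[i]) - ui + Isyn + In) / pC[i];
        du = pa[i] * (pb[i] * (vi - pvr[i]) - ui);
      } else {
        dv = (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Isyn + In) / pC[i];
        du = pa[i] * (pb[i] * vi - ui);
      }
      double u_new = ui + dt * du;
      double v_new = vi + dt * dv;
      if (!std::isfinite(v_new) || !std::isfinite(u_new)) {
        stop("numeric blow-up (non-finite state) in neuron %d at t = %.2f ms",
             i + 1, t_now);
      }
      if (v_new >= pvp[i]) {
        v[i] = pc[i];
        u[i] = u_new + pd[i];
        double snew = s[i] - sdec;
        s[i] = snew < 0.0 ? 0.0 : snew;
        inS.push_back(i);
        if (record_spikes) {
          sp_step_out.push_back(t);
          sp_id_out.push_back(i + 1);
        }
      } else {
        if (std::fabs(v_new) > 10.0 * std::fabs(pvp[i])) {
          stop("numeric blow-up (|v| = %.1f mV) in neuron %d at t = %.2f ms",
               v_new, i + 1, t_now);
        }
        v[i] = v_new;
        u[i] = u_new;
      }
    }
    if (!inS.empty()) {
      std::vector<char> isS(N, 0);
      for (size_t a = 0; a < inS.size(); ++a) isS[inS[a]] = 1;
      // 6. plasticity, all spikers against pre-step spike history
      for (size_t a = 0; a < inS.size(); ++a) {
        const int j = inS[a];
        // potentiation on plastic afferent excitatory synapses i -> j
        for (int i = 0; i < N; ++i) {
          if (ruleE(i, j) == 1) {
            double tpre = isS[i] ? t_now : t_last[i];
            if (tpre >= 0.0) {
              double base = dltp + lastLTD[(size_t)i + (size_t)N * j];
              if (base < 0.0) base = 0.0;
              double dw = base * std::exp(-(t_now - tpre) / tau_ltp);
              We(i, j) = clampw(We(i, j) + dw, wmin_e, wmax_e);
            }
          }
        }
        // depression on plastic efferent excitatory synapses j -> k
        for (int k = 0; k < N; ++k) {
          if (ruleE(j, k) == 1 && !isS[k] && t_last[k] >= 0.0) {
            double dw = -dltd * std::exp(-(t_now - t_last[k]) / tau_ltd);
            lastLTD[(size_t)j + (size_t)N * k] = dw;
            We(j, k) = clampw(We(j, k) + dw, wmin_e, wmax_e);
          }
        }
        // symmetric top-hat on afferent inhibitory synapses i -> j
        for (int i = 0; i < N; ++i) {
          int r = ruleI(i, j);
          if (r > 0) {
            double tpre = isS[i] ? t_now : t_last[i];
            if (tpre >= 0.0) {
              double dw = tophat_eval(t_now - tpre, ihwin(r - 1, 0),
                                      ihwin(r - 1, 1), ihwin(r - 1, 2),
                                      ihwin(r - 1, 3));
              Wi(i, j) = clampw(Wi(i, j) + dw, 0.0, wmax_i);
            }
          }
        }
        // symmetric top-hat on efferent inhibitory synapses j -> k
        for (int k = 0; k < N; ++k) {
          int r = ruleI(j, k);
          if (r > 0) {
            double tpost = isS[k] ? t_now : t_last[k];
            if (tpost >= 0.0) {
              double dw = tophat_eval(t_now - tpost, ihwin(r - 1, 0),
                                      ihwin(r - 1, 1), ihwin(r - 1, 2),
                                      ihwin(r - 1, 3));
              Wi(j, k) = clampw(Wi(j, k) + dw, 0.0, wmax_i);
            }
          }
        }
      }
      // 7. enqueue recurrent deliveries with post-update weights
      for (size_t a = 0; a < inS.size(); ++a) {
        const int j = inS[a];
        for (int k = 0; k < N; ++k) {
          if (Ae(j, k)) {
            int te = t + DeS(j, k);
            if (te < n_total) ringE[te % L][k] += We(j, k);
          }
        }
        for (int k = 0; k < N; ++k) {
          if (Ai(j, k)) {
            int te = t + DiS(j, k);
            if (te < n_total) {
              if (ipool[j] == 1) ringI1[te % L][k] += Wi(j, k);
              else ringI2[te % L][k] += Wi(j, k);
            }
          }
        }
        t_last[j] = t_now;
      }
    }
    // 8. homeostatic drift
    for (int i = 0; i < N; ++i) s[i] += omegaD[i] * drift;
    // 9. periodic weight snapshot
    if (snap_period > 0 && (t + 1) % snap_period == 0) {
      snaps.push_back(List::create(_["time_s"] = t_now / 1000.0,
                                   _["We"] = clone(We),
                                   _["Wi"] = clone(Wi)));
    }
    if (t % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["sp_step"] = wrap(sp_step_out), _["sp_id"] = wrap(sp_id_out),
    _["snapshots"] = snaps,
    _["v"] = wrap(v), _["u"] = wrap(u), _["s"] = wrap(s),
    _["Ge"] = wrap(Ge), _["Gi1"] = wrap(Gi1), _["Gi2"] = wrap(Gi2),
    _["We"] = We, _["Wi"] = Wi);
}
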
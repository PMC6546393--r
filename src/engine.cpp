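// Time-stepping engine for the rate network with Hebbian and structural
// plasticity. Forward Euler at fixed dt; one Gaussian noise value per neuron
// per step. Structural events (creation / weight-dependent deletion on the
// potential-synapse lattice) are sampled event-wise per step: candidate
// counts are binomial at the bounding hazards (b for creation, d0 for
// deletion) and deletion candidates are thinned by d(w)/d0, which reproduces
// the per-location Bernoulli semantics up to O((d0 dt)^2).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct StructParams {
  double d0, d1, w_off, beta;
  double del_rate(double w) const {
    return d1 + (d0 - d1) / (1.0 + std::exp(-beta * (w_off - w)));
  }
};

static inline int popcount16(uint16_t x) {
  int c = 0;
  while (x) { c += x & 1; x >>= 1; }
  return c;
}

// [[Rcpp::export]]
List engine_run(List par,
                NumericVector u0, double inh0, NumericVector f0,
                NumericVector iad0, double t0,
                IntegerVector syn_post, IntegerVector syn_pre,
                IntegerVector syn_slot, NumericVector syn_w,
                NumericVector syn_tc,
                NumericVector ev_start, NumericVector ev_end,
                NumericVector ev_amp, IntegerVector ev_ids,
                IntegerVector ev_ptr,
                IntegerVector group_index,
                double total_time, double snapshot_every, double record_every,
                bool hebbian_on, bool structural_on, bool log_events) {
  const double tau = par["tau"];
  const int n = as<int>(par["n_cells"]);
  const int s_max = as<int>(par["s_max"]);
  const double w_max = par["w_max"];
  const double w_inh = par["w_inh"];
  const double noise_sd = par["noise_sd"];
  const double b_day = par["b"];
  const double dt = par["dt"];
  const double ddecay = par["delta_decay"];
  const double dltp = par["delta_ltp"];
  const double dltd = par["delta_ltd"];
  const double tau_relax = par["tau_relax"];
  const double f_dep = par["f_dep"];
  const double alpha = par["alpha_adapt"];
  const double tau_adapt = par["tau_adapt"];
  const bool sfa = as<std::string>(par["adaptation_mode"]) ==
                   "spike_frequency_adaptation";
  StructParams sp{as<double>(par["d0"]), as<double>(par["d1"]),
                  as<double>(par["w_off"]), as<double>(par["beta"])};
  const double w0 = par["w0"];

  const long long nsteps = (long long)std::llround(total_time / dt);
  const long long rec_stride =
      std::max(1LL, (long long)std::llround(record_every / dt));
  const long long snap_stride =
      std::max(1LL, (long long)std::llround(snapshot_every / dt));

  // --- state ---
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> iad(iad0.begin(), iad0.end());
  double i_inh = inh0;
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i) v[i] = logistic(u[i]);

  // --- synapses (structure-of-arrays, swap-remove) ---
  std::vector<int> spost(syn_post.begin(), syn_post.end());   // 1-based
  std::vector<int> spre(syn_pre.begin(), syn_pre.end());
  std::vector<int> sslot(syn_slot.begin(), syn_slot.end());   // 1-based
  std::vector<double> sw(syn_w.begin(), syn_w.end());
  std::vector<double> stc(syn_tc.begin(), syn_tc.end());
  std::vector<uint16_t> occ((size_t)n * n, 0);
  if (s_max > 16) stop("engine supports s_max <= 16");
  for (size_t s = 0; s < spost.size(); ++s) {
    int p = (spost[s] - 1) * n + (spre[s] - 1);
    uint16_t bit = (uint16_t)(1u << (sslot[s] - 1));
    if (occ[p] & bit) stop("duplicate synapse slot in initial table");
    occ[p] |= bit;
  }
  const long long total_slots = (long long)n * (n - 1) * s_max;

  // --- stimulation events ---
  const int nev = ev_start.size();
  int ev_next = 0;
  std::vector<int> active;
  std::vector<double> istim(n, 0.0);
  bool stim_dirty = true;

  // --- groups for activity recording ---
  int ngroup = 0;
  for (int i = 0; i < n; ++i) ngroup = std::max(ngroup, group_index[i]);
  std::vector<int> gsize(ngroup + 1, 0);
  for (int i = 0; i < n; ++i) gsize[group_index[i]]++;

  // --- recorders ---
  long long nrec = nsteps / rec_stride;
  NumericVector rec_t(nrec);
  NumericMatrix rec_rate(nrec, ngroup + 1);
  long long nsnap = nsteps / snap_stride + 1;
  std::vector<double> snap_t; snap_t.reserve(nsnap);
  std::vector<int> snap_ptr; snap_ptr.push_back(0);
  std::vector<int> snap_post, snap_pre, snap_slot;
  std::vector<double> snap_w, snap_tc;
  std::vector<double> evlog_t; std::vector<int> evlog_kind, evlog_post,
      evlog_pre, evlog_slot;

  auto take_snapshot = [&](double tnow) {
    snap_t.push_back(tnow);
    snap_post.insert(snap_post.end(), spost.begin(), spost.end());
    snap_pre.insert(snap_pre.end(), spre.begin(), spre.end());
    snap_slot.insert(snap_slot.end(), sslot.begin(), sslot.end());
    snap_w.insert(snap_w.end(), sw.begin(), sw.end());
    snap_tc.insert(snap_tc.end(), stc.begin(), stc.end());
    snap_ptr.push_back((int)snap_post.size());
  };

  const double p_create_step = -std::expm1(-(b_day / 86400.0) * dt);
  const double q_del_step = -std::expm1(-(sp.d0 / 86400.0) * dt);
  const double dt_tau = dt / tau;

  std::vector<double> irec(n), fv(n);
  // Hebbian per-regime Euler coefficients: w <- w + A*w + B
  // regimes: 0 = decay (both low), 1 = LTD (mixed, incl. ties), 2 = LTP
  const double A[3] = {-ddecay * dt, -dltd * dt, -dltp * dt};
  const double B[3] = {0.0, 0.0, dltp * dt * w_max};
  // neuron activity code: 0 low (v<0.5), 1 tie, 2 high; pair code -> regime
  uint8_t regime_tab[9];
  for (int a = 0; a < 3; ++a)
    for (int bcode = 0; bcode < 3; ++bcode)
      regime_tab[a * 3 + bcode] =
          (a == 0 && bcode == 0) ? 0 : (a == 2 && bcode == 2) ? 2 : 1;
  std::vector<uint8_t> code(n);

  RNGScope rng;

  for (long long step = 0; step < nsteps; ++step) {
    double tnow = t0 + step * dt;
    if (step % snap_stride == 0) take_snapshot(tnow);

    // -- stimulation bookkeeping --
    while (ev_next < nev && ev_start[ev_next] <= tnow + 1e-9) {
      active.push_back(ev_next++);
      stim_dirty = true;
    }
    for (size_t a = 0; a < active.size();) {
      if (ev_end[active[a]] <= tnow + 1e-9) {
        active[a] = active.back(); active.pop_back(); stim_dirty = true;
      } else ++a;
    }
    if (stim_dirty) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int a : active)
        for (int k = ev_ptr[a]; k < ev_ptr[a + 1]; ++k)
          istim[ev_ids[k] - 1] += ev_amp[a];
      stim_dirty = false;
    }

    // -- recurrent current + Hebbian update (step-start rates) --
    for (int i = 0; i < n; ++i) {
      code[i] = v[i] < 0.5 ? 0 : (v[i] > 0.5 ? 2 : 1);
      irec[i] = 0.0;
      fv[i] = f[i] * v[i];
    }
    const size_t nsyn = sw.size();
    const int *pr = spre.data(), *po = spost.data();
    double *wp = sw.data();
    if (hebbian_on) {
      for (size_t s = 0; s < nsyn; ++s) {
        const int pre = pr[s] - 1, post = po[s] - 1;
        const double w = wp[s];
        irec[post] += w * fv[pre];
        const int r = regime_tab[code[pre] * 3 + code[post]];
        wp[s] = w + A[r] * w + B[r];
      }
    } else {
      for (size_t s = 0; s < nsyn; ++s)
        irec[po[s] - 1] += wp[s] * fv[pr[s] - 1];
    }

    // -- membrane update (step-start rates and inhibition), then rates,
    //    then inhibition and adaptation from the updated rates. The
    //    sequential sweep keeps the fast membrane-inhibition loop of the
    //    discrete map stable at dt = 0.1 s; the parallel variant is
    //    unstable for quiet networks of this size and produces a spurious
    //    synchronized bursting mode. --
    if (noise_sd > 0.0) {
      for (int i = 0; i < n; ++i) {
        double tot = irec[i] + i_inh + istim[i] + noise_sd * norm_rand();
        if (sfa) tot += iad[i];
        u[i] += dt_tau * (-u[i] + tot);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double tot = irec[i] + i_inh + istim[i];
        if (sfa) tot += iad[i];
        u[i] += dt_tau * (-u[i] + tot);
      }
    }
    double sum_v = 0.0;
    for (int i = 0; i < n; ++i) { v[i] = logistic(u[i]); sum_v += v[i]; }
    i_inh += dt_tau * (-i_inh - w_inh * sum_v);
    if (sfa) {
      for (int i = 0; i < n; ++i)
        iad[i] += (dt / tau_adapt) * (-iad[i] - alpha * v[i]);
    } else {
      for (int i = 0; i < n; ++i)
        f[i] += dt * ((1.0 - f[i]) / tau_relax - f_dep * f[i] * v[i]);
    }

    // -- structural plasticity (deletions before creations) --
    if (structural_on) {
      long long nocc = (long long)sw.size();
      if (nocc > 0) {
        int ncand = (int)R::rbinom((double)nocc, q_del_step);
        for (int c = 0; c < ncand && !sw.empty(); ++c) {
          size_t idx = (size_t)(unif_rand() * sw.size());
          if (idx >= sw.size()) idx = sw.size() - 1;
          if (unif_rand() * sp.d0 < sp.del_rate(sw[idx])) {
            int p = (spost[idx] - 1) * n + (spre[idx] - 1);
            occ[p] &= ~(uint16_t)(1u << (sslot[idx] - 1));
            if (log_events) {
              evlog_t.push_back(tnow + dt); evlog_kind.push_back(-1);
              evlog_post.push_back(spost[idx]); evlog_pre.push_back(spre[idx]);
              evlog_slot.push_back(sslot[idx]);
            }
            spost[idx] = spost.back(); spost.pop_back();
            spre[idx] = spre.back(); spre.pop_back();
            sslot[idx] = sslot.back(); sslot.pop_back();
            sw[idx] = sw.back(); sw.pop_back();
            stc[idx] = stc.back(); stc.pop_back();
          }
        }
      }
      long long nvac = total_slots - (long long)sw.size();
      if (nvac > 0) {
        int ncre = (int)R::rbinom((double)nvac, p_create_step);
        for (int c = 0; c < ncre; ++c) {
          // rejection-sample a vacant location uniformly
          int ii, jj, p, tries = 0;
          uint16_t bits;
          for (;;) {
            ii = (int)(unif_rand() * n); if (ii >= n) ii = n - 1;
            jj = (int)(unif_rand() * n); if (jj >= n) jj = n - 1;
            if (ii == jj) continue;
            p = ii * n + jj;
            bits = occ[p];
            int vac = s_max - popcount16(bits);
            if (unif_rand() * s_max < vac) break;
            if (++tries > 100000) stop("vacant-slot sampling stalled");
          }
          int k;
          do { k = (int)(unif_rand() * s_max); if (k >= s_max) k = s_max - 1; }
          while (bits & (1u << k));
          occ[p] |= (uint16_t)(1u << k);
          spost.push_back(ii + 1); spre.push_back(jj + 1);
          sslot.push_back(k + 1); sw.push_back(w0);
          stc.push_back(tnow + dt);
          if (log_events) {
            evlog_t.push_back(tnow + dt); evlog_kind.push_back(1);
            evlog_post.push_back(ii + 1); evlog_pre.push_back(jj + 1);
            evlog_slot.push_back(k + 1);
          }
        }
      }
    }

    // -- recording / health check --
    if ((step + 1) % rec_stride == 0) {
      long long r = (step + 1) / rec_stride - 1;
      rec_t[r] = t0 + (step + 1) * dt;
      std::vector<double> gsum(ngroup + 1, 0.0);
      for (int i = 0; i < n; ++i) gsum[group_index[i]] += v[i];
      for (int g = 0; g <= ngroup; ++g)
        rec_rate(r, g) = gsize[g] ? gsum[g] / gsize[g] : NA_REAL;
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(u[i]))
          stop("non-finite membrane potential at t = %f s (neuron %d)",
               t0 + (step + 1) * dt, i + 1);
      if ((step + 1) % (rec_stride * 600) == 0) checkUserInterrupt();
    }
  }
  if (nsteps % snap_stride == 0 && nsteps > 0) take_snapshot(t0 + nsteps * dt);
  if (nsteps == 0 && snap_t.empty()) take_snapshot(t0);

  List final_state = List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["i_inh"] = i_inh,
      _["f"] = NumericVector(f.begin(), f.end()),
      _["i_ad"] = NumericVector(iad.begin(), iad.end()),
      _["t"] = t0 + nsteps * dt);
  List final_syn = List::create(
      _["post"] = IntegerVector(spost.begin(), spost.end()),
      _["pre"] = IntegerVector(spre.begin(), spre.end()),
      _["slot"] = IntegerVector(sslot.begin(), sslot.end()),
      _["w"] = NumericVector(sw.begin(), sw.end()),
      _["t_create"] = NumericVector(stc.begin(), stc.end()));
  List snaps = List::create(
      _["t"] = NumericVector(snap_t.begin(), snap_t.end()),
      _["ptr"] = IntegerVector(snap_ptr.begin(), snap_ptr.end()),
      _["post"] = IntegerVector(snap_post.begin(), snap_post.end()),
      _["pre"] = IntegerVector(snap_pre.begin(), snap_pre.end()),
      _["slot"] = IntegerVector(snap_slot.begin(), snap_slot.end()),
      _["w"] = NumericVector(snap_w.begin(), snap_w.end()),
      _["t_create"] = NumericVector(snap_tc.begin(), snap_tc.end()));
  List evlog = List::create(
      _["t"] = NumericVector(evlog_t.begin(), evlog_t.end()),
      _["kind"] = IntegerVector(evlog_kind.begin(), evlog_kind.end()),
      _["post"] = IntegerVector(evlog_post.begin(), evlog_post.end()),
      _["pre"] = IntegerVector(evlog_pre.begin(), evlog_pre.end()),
      _["slot"] = IntegerVector(evlog_slot.begin(), evlog_slot.end()));
  return List::create(_["state"] = final_state, _["synapses"] = final_syn,
                      _["rec_t"] = rec_t, _["rec_rate"] = rec_rate,
                      _["snapshots"] = snaps, _["events"] = evlog);
}
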
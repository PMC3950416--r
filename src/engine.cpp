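#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven simulation of a network of single-compartment Hodgkin-Huxley
// neurons with exponential-decay conductance synapses and per-edge
// transmission delays. Input cells (kind 0) are pure spike sources whose
// spike times are supplied; HH cells (kind 1) are integrated with
// exponential-Euler gating and forward-Euler voltage at fixed dt.
//
// Step semantics, chosen to match the R reference stepper advanceNeuron():
// deliveries due at step k are added to the conductances first, then the
// step integrates with start-of-step currents and decays the conductances,
// so a conductance increment delivered at t decays over [t, t+dt).
//
// Units: time ms, voltage mV, channel densities mS/cm2, capacitance uF/cm2,
// synaptic conductances uS, point currents nA, membrane area cm2.

struct Delivery {
  int tgt;      // hh index
  double w;     // conductance increment, uS
  bool gaba;
};

// Rate functions of the squid-axon HH channels, absolute voltage convention.
static inline double alpha_m(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// [[Rcpp::export]]
List cs_engine_run(IntegerVector cell_kind,        // per global cell: 0 input, 1 HH
                   NumericMatrix state0,           // n_hh x 6: v m h n gA gG
                   IntegerVector src_ptr,          // CSR over global source ids, length n+1
                   IntegerVector syn_tgt,          // global target ids (must be HH)
                   NumericVector syn_w,
                   IntegerVector syn_dsteps,
                   IntegerVector syn_gaba,
                   IntegerVector in_cell,          // input spikes: global cell ids
                   NumericVector in_time,          //   sorted ascending, ms
                   double dt, double t_end,
                   NumericVector i_inj,            // nA per hh cell
                   List P,
                   IntegerVector record_hh)        // hh indices for voltage traces
{
  const int n_total = cell_kind.size();
  std::vector<int> hh_of(n_total, -1);
  std::vector<int> global_of;
  for (int i = 0; i < n_total; ++i)
    if (cell_kind[i] == 1) { hh_of[i] = (int)global_of.size(); global_of.push_back(i); }
  const int n_hh = (int)global_of.size();
  if (n_hh != state0.nrow()) stop("state0 rows must equal number of HH cells");
  if (src_ptr.size() != n_total + 1) stop("src_ptr must have length n_cells + 1");

  const double cm      = as<double>(P["cm"]);
  const double gpas    = as<double>(P["g_pas"]);
  const double eleak   = as<double>(P["e_leak"]);
  const double gna     = as<double>(P["g_na"]);
  const double ena     = as<double>(P["e_na"]);
  const double gk      = as<double>(P["g_k"]);
  const double ek      = as<double>(P["e_k"]);
  const double area    = as<double>(P["area_cm2"]);
  const double tau_a   = as<double>(P["tau_ampa"]);
  const double e_a     = as<double>(P["e_ampa"]);
  const double tau_g   = as<double>(P["tau_gaba"]);
  const double e_g     = as<double>(P["e_gaba"]);
  const double vth     = as<double>(P["v_thresh"]);
  const double refrac  = as<double>(P["refractory_ms"]);

  const double dec_a = std::exp(-dt / tau_a);
  const double dec_g = std::exp(-dt / tau_g);
  const double nA_to_uAcm2 = 1e-3 / area;

  // gating lookup tables on a 0.01 mV grid (max table error << integration error)
  const double v_lo = -120.0, v_hi = 80.0;
  const int ntab = 20001;
  std::vector<double> m_inf(ntab), m_fac(ntab), h_inf(ntab), h_fac(ntab),
                      n_inf(ntab), n_fac(ntab);
  for (int j = 0; j < ntab; ++j) {
    double vv = v_lo + j * 0.01;
    double a = alpha_m(vv), b = beta_m(vv);
    m_inf[j] = a / (a + b); m_fac[j] = std::exp(-dt * (a + b));
    a = alpha_h(vv); b = beta_h(vv);
    h_inf[j] = a / (a + b); h_fac[j] = std::exp(-dt * (a + b));
    a = alpha_n(vv); b = beta_n(vv);
    n_inf[j] = a / (a + b); n_fac[j] = std::exp(-dt * (a + b));
  }

  std::vector<double> v(n_hh), m(n_hh), h(n_hh), nn(n_hh), gA(n_hh), gG(n_hh);
  for (int i = 0; i < n_hh; ++i) {
    v[i] = state0(i, 0); m[i] = state0(i, 1); h[i] = state0(i, 2);
    nn[i] = state0(i, 3); gA[i] = state0(i, 4); gG[i] = state0(i, 5);
  }
  std::vector<double> refrac_until(n_hh, -1e30);
  std::vector<double> last_spike(n_hh, NA_REAL);

  const int n_steps = (int)std::llround(t_end / dt);
  int max_d = 1;
  for (int e = 0; e < syn_dsteps.size(); ++e)
    if (syn_dsteps[e] > max_d) max_d = syn_dsteps[e];
  const int D = max_d + 1;
  std::vector< std::vector<Delivery> > ring(D);

  const int n_in = in_cell.size();
  std::vector<int> in_step(n_in);
  for (int e = 0; e < n_in; ++e) {
    int s = (int)std::llround(in_time[e] / dt);
    in_step[e] = s < 1 ? 1 : s;
  }
  int in_ptr = 0;

  std::vector<int> spike_cell_out;     // global ids
  std::vector<double> spike_time_out;

  const int n_rec = record_hh.size();
  NumericMatrix vtrace(n_rec > 0 ? n_steps : 0, n_rec);

  for (int k = 1; k <= n_steps; ++k) {
    const double t = k * dt;
    const int slot = k % D;
    std::vector<Delivery> &due = ring[slot];
    for (size_t q = 0; q < due.size(); ++q) {
      if (due[q].gaba) gG[due[q].tgt] += due[q].w; else gA[due[q].tgt] += due[q].w;
    }
    due.clear();
    // input spikes at this step: schedule their synaptic deliveries
    while (in_ptr < n_in && in_step[in_ptr] <= k) {
      const int c = in_cell[in_ptr];
      for (int e = src_ptr[c]; e < src_ptr[c + 1]; ++e) {
        int ds = syn_dsteps[e]; if (ds < 1) ds = 1;
        Delivery d; d.tgt = hh_of[syn_tgt[e]]; d.w = syn_w[e]; d.gaba = syn_gaba[e] != 0;
        ring[(k + ds) % D].push_back(d);
      }
      ++in_ptr;
    }
    for (int i = 0; i < n_hh; ++i) {
      const double vi = v[i];
      double vc = vi < v_lo ? v_lo : (vi > v_hi ? v_hi : vi);
      const int j = (int)((vc - v_lo) * 100.0 + 0.5);
      const double ina = gna * m[i] * m[i] * m[i] * h[i] * (vi - ena);
      const double ik  = gk * nn[i] * nn[i] * nn[i] * nn[i] * (vi - ek);
      const double il  = gpas * (vi - eleak);
      const double isyn = (gA[i] * (vi - e_a) + gG[i] * (vi - e_g)) * nA_to_uAcm2;
      const double iin  = i_inj[i] * nA_to_uAcm2;
      const double vnew = vi + dt * (-(ina + ik + il + isyn) + iin) / cm;
      m[i]  = m_inf[j] + (m[i]  - m_inf[j]) * m_fac[j];
      h[i]  = h_inf[j] + (h[i]  - h_inf[j]) * h_fac[j];
      nn[i] = n_inf[j] + (nn[i] - n_inf[j]) * n_fac[j];
      gA[i] *= dec_a; gG[i] *= dec_g;
      if (!std::isfinite(vnew))
        stop("integration diverged: non-finite membrane voltage in cell %d at t = %f ms (dt = %f)",
             global_of[i], t, dt);
      if (vnew >= vth && vi < vth && t >= refrac_until[i]) {
        refrac_until[i] = t + refrac;
        last_spike[i] = t;
        const int g = global_of[i];
        spike_cell_out.push_back(g);
        spike_time_out.push_back(t);
        for (int e = src_ptr[g]; e < src_ptr[g + 1]; ++e) {
          int ds = syn_dsteps[e]; if (ds < 1) ds = 1;
          Delivery d; d.tgt = hh_of[syn_tgt[e]]; d.w = syn_w[e]; d.gaba = syn_gaba[e] != 0;
          ring[(k + ds) % D].push_back(d);
        }
      }
      v[i] = vnew;
    }
    if (n_rec > 0)
      for (int r = 0; r < n_rec; ++r) vtrace(k - 1, r) = v[record_hh[r]];
  }

  NumericMatrix state_out(n_hh, 6);
  for (int i = 0; i < n_hh; ++i) {
    state_out(i, 0) = v[i]; state_out(i, 1) = m[i]; state_out(i, 2) = h[i];
    state_out(i, 3) = nn[i]; state_out(i, 4) = gA[i]; state_out(i, 5) = gG[i];
  }
  return List::create(_["spike_cell"] = wrap(spike_cell_out),
                      _["spike_time"] = wrap(spike_time_out),
                      _["state"] = state_out,
                      _["last_spike"] = wrap(last_spike),
                      _["vtrace"] = vtrace);
}
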
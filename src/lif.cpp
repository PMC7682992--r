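#include <Rcpp.h>
using namespace Rcpp;

// Per-dt leaky integrate-and-fire circuit: pyramidal output cell, a
// feedforward interneuron (FSIN) inhibiting it, and an optional
// interneuron-selective interneuron (ISI) inhibiting the FSIN. All cells
// receive the same two input spike trains (hippocampal, noise), supplied
// as per-bin spike counts. Synapses are current-based exponential kernels
// (tau_e excitatory, tau_i inhibitory); the membrane integrates with Euler
// steps, tau_m dV/dt = -V + E + I. Spikes reset V and enforce an absolute
// refractory period; a spike emitted in bin t reaches its target in bin
// t + 1. The plain-R reference loop in R/lif.R mirrors these update
// equations statement for statement.
//
// [[Rcpp::export]]
List lif_simulate_cpp(IntegerVector hpc, IntegerVector noise, List params) {
  const int n = hpc.size();
  if (noise.size() != n) stop("input trains must have equal length");

  const double dt = as<double>(params["dt_ms"]);
  const double tau_m = as<double>(params["tau_m"]);
  const double tau_e = as<double>(params["tau_e"]);
  const double tau_i = as<double>(params["tau_i"]);
  const double v_th = as<double>(params["v_thresh"]);
  const double v_reset = as<double>(params["v_reset"]);
  const int refrac = (int) std::ceil(as<double>(params["refrac_ms"]) / dt);

  const double w_hpc_pyr = as<double>(params["w_hpc_pyr"]);
  const double w_noise_pyr = as<double>(params["w_noise_pyr"]);
  const double w_hpc_fsin = as<double>(params["w_hpc_fsin"]);
  const double w_noise_fsin = as<double>(params["w_noise_fsin"]);
  const double w_fsin_pyr = as<double>(params["w_fsin_pyr"]);
  const double w_hpc_isi = as<double>(params["w_hpc_isi"]);
  const double w_noise_isi = as<double>(params["w_noise_isi"]);
  const double w_isi_fsin = as<double>(params["w_isi_fsin"]);

  const double de = std::exp(-dt / tau_e);
  const double di = std::exp(-dt / tau_i);
  const double a = dt / tau_m;

  double e_pyr = 0, e_fsin = 0, e_isi = 0;
  double i_pyr = 0, i_fsin = 0;
  double v_pyr = 0, v_fsin = 0, v_isi = 0;
  int r_pyr = 0, r_fsin = 0, r_isi = 0;
  int s_fsin_prev = 0, s_isi_prev = 0;

  std::vector<int> sp_pyr, sp_fsin, sp_isi;

  for (int t = 0; t < n; ++t) {
    const int nh = hpc[t], nn = noise[t];

    e_isi = e_isi * de + w_hpc_isi * nh + w_noise_isi * nn;
    e_fsin = e_fsin * de + w_hpc_fsin * nh + w_noise_fsin * nn;
    e_pyr = e_pyr * de + w_hpc_pyr * nh + w_noise_pyr * nn;
    i_fsin = i_fsin * di + w_isi_fsin * s_isi_prev;
    i_pyr = i_pyr * di + w_fsin_pyr * s_fsin_prev;

    int s_isi = 0, s_fsin = 0;

    if (r_isi > 0) { --r_isi; v_isi = v_reset; }
    else {
      v_isi += a * (-v_isi + e_isi);
      if (v_isi >= v_th) { s_isi = 1; sp_isi.push_back(t + 1); v_isi = v_reset; r_isi = refrac; }
    }
    if (r_fsin > 0) { --r_fsin; v_fsin = v_reset; }
    else {
      v_fsin += a * (-v_fsin + e_fsin + i_fsin);
      if (v_fsin >= v_th) { s_fsin = 1; sp_fsin.push_back(t + 1); v_fsin = v_reset; r_fsin = refrac; }
    }
    if (r_pyr > 0) { --r_pyr; v_pyr = v_reset; }
    else {
      v_pyr += a * (-v_pyr + e_pyr + i_pyr);
      if (v_pyr >= v_th) { sp_pyr.push_back(t + 1); v_pyr = v_reset; r_pyr = refrac; }
    }
    if (!std::isfinite(v_pyr) || !std::isfinite(v_fsin)) stop("non-finite membrane potential");

    s_isi_prev = s_isi;
    s_fsin_prev = s_fsin;
  }

  return List::create(
    _["pyr"] = wrap(sp_pyr),
    _["fsin"] = wrap(sp_fsin),
    _["isi"] = wrap(sp_isi)
  );
}
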
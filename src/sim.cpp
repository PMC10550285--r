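#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Full forward integration of the CA3-DG-interneuron network.
//
// Populations are concatenated as CA3 (nC), DG (nD), CA3-interneurons (nIc),
// DG-interneurons (nId); global ids are 1-based in that order.
//
// Per-step order of operations (the R reference simulator follows the same
// contract):
//   1. spikes scheduled for this step are delivered: conductance jumps
//      (1/N_pre) * W[,j] * s_D[j] (s_D = 1 for non-CA3 sources);
//   2. currents are computed from the jumped conductances and the
//      start-of-step state: I = (V_E - v) g_E + (V_I - v) g_I + I_S - I_theta,
//      with I_S = J_S * s_F^2 for CA3 only;
//   3. forward-Euler update of v and u; threshold crossings (v < 30 <= v')
//      register a spike at the end-of-step time, reset v <- c_reset,
//      u <- u + d, deplete s_D (CA3), and enqueue delivery 2 ms later;
//   4. conductances decay by (1 - dt/tau); s_D recovers; s_F relaxes under
//      the STF rule driven by this step's J_S.
//
// Spikes emitted at end of step s are delivered at the start of step
// s + 1 + delay_steps, i.e. exactly tau_0 after the recorded spike time.

// [[Rcpp::export]]
List sim_core(NumericMatrix Wcc, NumericMatrix Wdc, NumericMatrix Wcd,
              NumericMatrix Wic, NumericMatrix Wid,
              double w_ca3_inh, double w_dg_inh,
              NumericMatrix ca3_centers, NumericVector ca3_psi,
              NumericMatrix traj, List prm) {
  const int nC = as<int>(prm["n_ca3"]);
  const int nD = as<int>(prm["n_dg"]);
  const int nIc = as<int>(prm["n_inh_ca3"]);
  const int nId = as<int>(prm["n_inh_dg"]);
  const int n_steps = traj.nrow();
  const double dt = as<double>(prm["dt"]);

  const double tauE = as<double>(prm["tau_E"]), tauI = as<double>(prm["tau_I"]);
  const double tauF = as<double>(prm["tau_F"]), tauD = as<double>(prm["tau_D"]);
  const double VE = as<double>(prm["V_E"]), VI = as<double>(prm["V_I"]);
  const double theta_amp = as<double>(prm["theta_amp"]);
  const double theta_period = as<double>(prm["theta_period"]);
  const double mec_shift = as<double>(prm["mec_shift"]);   // radians
  const double Apos = as<double>(prm["A_pos"]), Adir = as<double>(prm["A_dir"]);
  const double r2 = std::pow(as<double>(prm["input_radius"]), 2);
  const double S0F = as<double>(prm["S0F"]), S1F = as<double>(prm["S1F"]);
  const double PhiF = as<double>(prm["Phi_F"]);
  const double UD = as<double>(prm["U_D"]);
  const bool std_mult = as<std::string>(prm["std_mode"]) == "multiplicative";
  // "emission": the release resource is captured when the spike is emitted
  // (before its own depletion, the Tsodyks-Markram convention);
  // "delivery": s_D is looked up when the spike arrives tau_0 later.
  const bool rel_emission = as<std::string>(prm["std_release"]) == "emission";
  const bool std_to_inh = as<bool>(prm["std_to_interneurons"]);
  const bool std_to_dg = as<bool>(prm["std_to_dg"]);
  const bool theta_to_inh = as<bool>(prm["theta_to_inhibitory"]);
  const bool dg_lesion = as<bool>(prm["dg_lesion"]);
  const int delay_steps = as<int>(prm["delay_steps"]);
  const double max_spikes = as<double>(prm["max_spikes"]);
  // divisor of the conductance jumps from DG-source spikes: the global
  // presynaptic place-cell count N_J (default) or the DG layer size
  const double dg_norm = as<double>(prm["dg_norm"]);

  // Izhikevich parameters: excitatory for CA3+DG, inhibitory for interneurons
  const double aE = as<double>(prm["a_exc"]), bE = as<double>(prm["b_exc"]);
  const double cE = as<double>(prm["c_exc"]), dE = as<double>(prm["d_exc"]);
  const double aI = as<double>(prm["a_inh"]), bI = as<double>(prm["b_inh"]);
  const double cI = as<double>(prm["c_inh"]), dI = as<double>(prm["d_inh"]);

  const int nE = nC + nD;
  const int nTot = nE + nIc + nId;
  const int oD = nC, oIc = nE, oId = nE + nIc;   // population offsets

  // start every neuron at its resting fixed point: with u = b v the
  // v-nullcline gives 0.04 v^2 + (5 - b) v + 140 = 0 (stable lower root);
  // -70 mV for the excitatory parameters, about -64.4 mV for inhibitory
  std::vector<double> v(nTot), u(nTot), gE(nTot, 0.0), gI(nTot, 0.0);
  for (int i = 0; i < nTot; ++i) {
    const double b = (i < nE) ? bE : bI;
    const double disc = (5.0 - b) * (5.0 - b) - 4.0 * 0.04 * 140.0;
    v[i] = (-(5.0 - b) - std::sqrt(disc)) / (2.0 * 0.04);
    u[i] = b * v[i];
  }
  std::vector<double> sF(nC, S0F), sD(nC, 1.0), Js(nC, 0.0);

  struct Ev { int id; double rel; };
  const int qlen = delay_steps + 2;
  std::vector< std::vector<Ev> > queue(qlen);

  std::vector<int> rec_id;
  std::vector<double> rec_t;
  rec_id.reserve(1 << 16);
  rec_t.reserve(1 << 16);

  const double decE = 1.0 - dt / tauE, decI = 1.0 - dt / tauI;
  const double *px = &traj(0, 0), *py = &traj(0, 1), *ph = &traj(0, 2);
  const double *cx = &ca3_centers(0, 0), *cy = &ca3_centers(0, 1);

  const bool has_cc = Wcc.nrow() > 0, has_dc = Wdc.nrow() > 0;
  const bool has_cd = Wcd.nrow() > 0, has_ic = Wic.nrow() > 0;
  const bool has_id = Wid.nrow() > 0;

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // 1. deliver spikes due this step
    std::vector<Ev> &due = queue[s % qlen];
    for (size_t q = 0; q < due.size(); ++q) {
      const int j = due[q].id;
      if (j < nC) {                       // CA3 source, STD applies
        const double rel = rel_emission ? due[q].rel : sD[j];
        if (has_cc) {
          const double *col = &Wcc(0, j);
          const double f = rel / nC;
          for (int i = 0; i < nC; ++i) gE[i] += col[i] * f;
        }
        if (has_dc && !dg_lesion) {
          const double *col = &Wdc(0, j);
          const double f = (std_to_dg ? rel : 1.0) / nC;
          for (int i = 0; i < nD; ++i) gE[oD + i] += col[i] * f;
        }
        if (nIc > 0 && w_ca3_inh > 0) {
          const double f = w_ca3_inh * (std_to_inh ? rel : 1.0) / nC;
          for (int i = 0; i < nIc; ++i) gE[oIc + i] += f;
        }
      } else if (j < nE) {                // DG source
        const int jd = j - oD;
        if (has_cd) {
          const double *col = &Wcd(0, jd);
          const double f = 1.0 / dg_norm;
          for (int i = 0; i < nC; ++i) gE[i] += col[i] * f;
        }
        if (nId > 0 && w_dg_inh > 0) {
          const double f = w_dg_inh / dg_norm;
          for (int i = 0; i < nId; ++i) gE[oId + i] += f;
        }
      } else if (j < nE + nIc) {          // CA3 interneuron
        if (has_ic) {
          const double *col = &Wic(0, j - oIc);
          const double f = 1.0 / nIc;
          for (int i = 0; i < nC; ++i) gI[i] += col[i] * f;
        }
      } else {                            // DG interneuron
        if (has_id) {
          const double *col = &Wid(0, j - oId);
          const double f = 1.0 / nId;
          for (int i = 0; i < nD; ++i) gI[oD + i] += col[i] * f;
        }
      }
    }
    due.clear();

    // sensory drive for CA3 (box field, directional gain, MEC theta gate)
    // entorhinal gate peaks mec_shift (radians of phase) after the theta peak
    const double Imec = 0.5 * (1.0 + std::cos(2.0 * M_PI * t / theta_period -
                                              mec_shift));
    const double Ith = theta_amp * (1.0 + std::cos(2.0 * M_PI * t /
                                                   theta_period)) / 2.0;
    const double x = px[s], y = py[s], hd = ph[s];
    for (int i = 0; i < nC; ++i) {
      const double ddx = cx[i] - x, ddy = cy[i] - y;
      if (ddx * ddx + ddy * ddy <= r2) {
        Js[i] = (Apos + Adir * std::exp(std::cos(hd - ca3_psi[i]) - 1.0)) * Imec;
      } else {
        Js[i] = 0.0;
      }
    }

    // 2.-3. currents, update, spike handling.  The intrinsic (quadratic)
    // and stimulus terms advance by forward Euler; the synaptic conductance
    // terms are taken semi-implicitly, which keeps the synaptic pull
    // bounded by the reversal potentials however large the conductances
    // get (forward Euler overshoots far below V_I under strong inhibition
    // and triggers artificial network-wide rebound bursts).
    const int dslot = (s + 1 + delay_steps) % qlen;
    for (int i = 0; i < nTot; ++i) {
      const bool exc = i < nE;
      double Iext = 0.0;
      if (i < nC) Iext += Js[i] * sF[i] * sF[i];
      if (exc || theta_to_inh) Iext -= Ith;
      const double vi = v[i];
      const double vstar =
        vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - u[i] + Iext);
      double vn = (vstar + dt * (gE[i] * VE + gI[i] * VI)) /
                  (1.0 + dt * (gE[i] + gI[i]));
      double un = u[i] + dt * (exc ? aE : aI) * ((exc ? bE : bI) * vi - u[i]);
      if (vi < 30.0 && vn >= 30.0) {
        rec_id.push_back(i + 1);
        rec_t.push_back(t + dt);
        Ev ev; ev.id = i; ev.rel = (i < nC) ? sD[i] : 1.0;
        queue[dslot].push_back(ev);
        vn = exc ? cE : cI;
        un += exc ? dE : dI;
        if (i < nC) {   // deplete now; recovery follows in stage 4
          sD[i] = std_mult ? sD[i] * (1.0 - UD) : std::max(sD[i] - UD, 0.0);
        }
      }
      if (!std::isfinite(vn) || !std::isfinite(un)) {
        stop("integration diverged at t = %f ms (neuron %d); reduce dt",
             t, i + 1);
      }
      v[i] = vn;
      u[i] = un;
    }
    if ((double)rec_id.size() > max_spikes) {
      if (as<bool>(prm["overflow_error"])) {
        stop("spike count exceeded max_spikes = %g; network likely unstable",
             max_spikes);
      }
      break;   // truncate: return the spikes recorded so far
    }

    // 4. decay conductances, recover s_D, relax s_F
    for (int i = 0; i < nTot; ++i) { gE[i] *= decE; gI[i] *= decI; }
    for (int i = 0; i < nC; ++i) {
      sD[i] += dt * (1.0 - sD[i]) / tauD;
      sF[i] += dt * ((S0F - sF[i]) / tauF + (S1F - sF[i]) * PhiF * Js[i]);
    }
  }

  return List::create(_["id"] = wrap(rec_id), _["t"] = wrap(rec_t),
                      _["s_D"] = wrap(sD), _["s_F"] = wrap(sF));
}
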
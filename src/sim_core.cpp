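#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step closed-loop stepper: breath-cycle state machine + PID pressure
// control + single-compartment R/C lung behind a quasi-static airway node.
// Mirrors the R reference implementation (control_tick(), step_lung(), ...)
// operation for operation; the two paths are cross-checked in the tests.
//
// Units are internal SI-ish: pressure cmH2O, volume L, flow L/s, time s.
// The pressure channel of the returned waveform is the SENSED pressure the
// controller acted on; flows and volume are physics truth.

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// airway pressure from flow balance at the patient wye (no transient term)
static inline double node_pressure(double q_in, double p_alv, bool exp_open,
                                   double peep, double R, double Re) {
  if (exp_open) {
    double p = (q_in + p_alv / R + peep / Re) / (1.0 / R + 1.0 / Re);
    if (p > peep) return p;
  }
  return p_alv + R * q_in;
}

// [[Rcpp::export]]
List sim_core(List cfg) {
  const double dtc = as<double>(cfg["dt_control"]);
  const double dtp = as<double>(cfg["dt_physics"]);
  const int nsub = as<int>(cfg["n_sub"]);
  const int n_cycle_ticks = as<int>(cfg["n_cycle_ticks"]);
  const int n_insp_ticks = as<int>(cfg["n_insp_ticks"]);
  const int refrac_ticks = as<int>(cfg["refrac_ticks"]);
  const int ndeb = as<int>(cfg["n_debounce"]);

  const double pip = as<double>(cfg["pip_target"]);
  const double peep = as<double>(cfg["peep_setting"]);
  const double sens = as<double>(cfg["trigger_sensitivity"]);
  const double hapa = as<double>(cfg["hapa_limit"]);
  const double fa = as<double>(cfg["flow_adjustment"]);

  const double kp = as<double>(cfg["kp"]);
  const double ki = as<double>(cfg["ki"]);
  const double kd = as<double>(cfg["kd"]);
  const double iclamp = as<double>(cfg["integral_clamp"]);
  const double dtau = as<double>(cfg["deriv_tau"]);

  const double C = as<double>(cfg["compliance_L"]);   // L/cmH2O
  const double R = as<double>(cfg["resistance"]);
  const double qmax = as<double>(cfg["qmax_Ls"]);
  const double Re = as<double>(cfg["exp_resistance"]);
  const double vtau = as<double>(cfg["valve_tau"]);

  const double pgain = as<double>(cfg["pressure_gain"]);
  const double poff = as<double>(cfg["pressure_offset"]);
  const double pnoise = as<double>(cfg["pressure_noise_sd"]);

  const IntegerVector ev_kind = cfg["ev_kind"];   // 1 effort, 2 transient
  const NumericVector ev_on = cfg["ev_onset"];
  const NumericVector ev_off = cfg["ev_end"];
  const NumericVector ev_mag = cfg["ev_magnitude"];
  const int n_ev = ev_kind.size();

  const int stop_mode = as<int>(cfg["stop_mode"]);  // 1 ticks, 2 cycles
  const R_xlen_t n_ticks = as<double>(cfg["n_ticks"]);
  const long n_cycles_target = as<double>(cfg["n_cycles_target"]);
  const R_xlen_t max_ticks = as<double>(cfg["max_ticks"]);

  // carried state (chunking support)
  List st = cfg["state"];
  double V = as<double>(st["volume"]);
  double qvalve = as<double>(st["qvalve"]);
  double t = as<double>(st["time"]);
  int tick_in_cycle = as<int>(st["tick_in_cycle"]);
  long cycle_index = as<double>(st["cycle_index"]);
  int phase = as<int>(st["phase"]);               // 1 INSPIRE, 2 EXPIRE
  double integ = as<double>(st["integral"]);
  double ef = as<double>(st["error_filtered"]);
  double eprev = as<double>(st["previous_error"]);
  bool insp_start = as<bool>(st["insp_start"]);
  bool override_on = as<bool>(st["override_active"]);
  int hapa_count = as<int>(st["hapa_count"]);
  int trig_count = as<int>(st["trigger_count"]);
  double last_paw = as<double>(st["last_paw"]);

  NumericMatrix wf(max_ticks, 10);
  std::vector<double> trig_times, hapa_on_times, hapa_clear_times;

  const double alpha = dtau > 0 ? dtc / (dtc + dtau) : 1.0;
  const double ilim = ki > 0 ? iclamp / ki : 0.0;

  R_xlen_t rec = 0;
  bool blew_up = false;
  bool done = false;

  for (R_xlen_t k = 0; !done; ++k) {
    if (stop_mode == 1 && k >= n_ticks) break;
    if (rec >= max_ticks) break;

    // -- sensor ----------------------------------------------------------
    double p_meas = pgain * last_paw + poff;
    if (pnoise > 0) p_meas += R::rnorm(0.0, pnoise);

    // -- safety override (absolute priority) -----------------------------
    bool was_override = override_on;
    bool cleared = false;
    if (p_meas > hapa) {
      hapa_count++;
      if (hapa_count >= ndeb) override_on = true;
    } else {
      hapa_count = 0;
      if (override_on) { override_on = false; cleared = true; }
    }
    if (override_on && !was_override) hapa_on_times.push_back(t);
    if (cleared) hapa_clear_times.push_back(t);
    bool hapa_active = override_on || cleared;
    if (override_on) phase = 2;  // cycling resumes at the next cycle boundary

    // -- cycle timing and breath triggering ------------------------------
    int new_cycle = 0;  // 0 none, 1 scheduled, 2 spontaneous
    if (!override_on && !cleared && tick_in_cycle >= n_cycle_ticks) {
      new_cycle = 1;                       // scheduled start wins ties
    } else if (phase == 2 && !override_on) {
      bool armed = tick_in_cycle >= refrac_ticks;
      if (armed && p_meas < peep - sens) trig_count++; else trig_count = 0;
      if (trig_count >= ndeb) {
        trig_count = 0;
        new_cycle = 2;
        trig_times.push_back(t);
      }
    }
    if (new_cycle) {
      tick_in_cycle = 0;
      phase = 1;
      cycle_index++;
      insp_start = true;
      trig_count = 0;
    }
    if (phase == 1 && tick_in_cycle >= n_insp_ticks) phase = 2;

    // -- output selection -------------------------------------------------
    double drive;
    bool exp_open;
    if (override_on || cleared) {
      drive = 0.0;
      exp_open = true;
    } else if (phase == 1) {
      double e = pip - p_meas;
      if (insp_start) { ef = e; eprev = e; insp_start = false; }
      else ef += alpha * (e - ef);
      double de = (ef - eprev) / dtc;
      eprev = ef;
      double icand = integ + e * dtc;
      double unsat = fa * kp * e + ki * icand + kd * de;
      if (!((unsat > 1.0 && e > 0.0) || (unsat < 0.0 && e < 0.0)))
        integ = icand;
      if (ki > 0) {
        if (integ > ilim) integ = ilim;
        if (integ < -ilim) integ = -ilim;
      }
      drive = clamp01(fa * kp * e + ki * integ + kd * de);
      exp_open = false;
    } else {
      drive = 0.0;
      exp_open = true;
    }
    tick_in_cycle++;

    // -- record (instantaneous state under the new outputs) ---------------
    double effort = 0.0, trans = 0.0;
    for (int i = 0; i < n_ev; ++i) {
      if (t >= ev_on[i] && t < ev_off[i]) {
        if (ev_kind[i] == 1) effort += ev_mag[i]; else trans += ev_mag[i];
      }
    }
    {
      double p_alv = V / C - effort;
      double paw = node_pressure(qvalve, p_alv, exp_open, peep, R, Re) + trans;
      double qexp = (exp_open && paw > peep) ? (paw - peep) / Re : 0.0;
      wf(rec, 0) = t;
      wf(rec, 1) = p_meas;
      wf(rec, 2) = qvalve * 60.0;
      wf(rec, 3) = qexp * 60.0;
      wf(rec, 4) = V * 1000.0;
      wf(rec, 5) = phase;
      wf(rec, 6) = drive;
      wf(rec, 7) = exp_open ? 1.0 : 0.0;
      wf(rec, 8) = hapa_active ? 1.0 : 0.0;
      wf(rec, 9) = new_cycle;
      rec++;
    }
    // in cycles mode the boundary tick of the next cycle is recorded, then
    // the tick is completed (physics + clock) so chunked runs resume cleanly
    bool stop_after = stop_mode == 2 && new_cycle &&
      cycle_index > n_cycles_target;

    // -- physics sub-steps -------------------------------------------------
    double qcmd = drive * qmax;
    for (int j = 0; j < nsub; ++j) {
      double tt = t + j * dtp;
      if (vtau > 0) qvalve += (dtp / vtau) * (qcmd - qvalve);
      else qvalve = qcmd;
      double eff = 0.0, tr = 0.0;
      for (int i = 0; i < n_ev; ++i) {
        if (tt >= ev_on[i] && tt < ev_off[i]) {
          if (ev_kind[i] == 1) eff += ev_mag[i]; else tr += ev_mag[i];
        }
      }
      double p_alv = V / C - eff;
      double paw = node_pressure(qvalve, p_alv, exp_open, peep, R, Re) + tr;
      double qlung = (paw - p_alv) / R;
      double qexp = (exp_open && paw > peep) ? (paw - peep) / Re : 0.0;
      (void)qexp;
      V += qlung * dtp;
      if (V < 0) V = 0;
      last_paw = paw;
    }
    t += dtc;

    if (!R_finite(V) || !R_finite(last_paw)) { blew_up = true; break; }
    if (stop_after) break;
  }

  List out_state = List::create(
      _["volume"] = V, _["qvalve"] = qvalve, _["time"] = t,
      _["tick_in_cycle"] = tick_in_cycle,
      _["cycle_index"] = (double)cycle_index, _["phase"] = phase,
      _["integral"] = integ, _["error_filtered"] = ef,
      _["previous_error"] = eprev, _["insp_start"] = insp_start,
      _["override_active"] = override_on, _["hapa_count"] = hapa_count,
      _["trigger_count"] = trig_count, _["last_paw"] = last_paw);

  return List::create(
      _["waveform"] = wf, _["n_recorded"] = (double)rec,
      _["state"] = out_state, _["blew_up"] = blew_up,
      _["trigger_times"] = wrap(trig_times),
      _["hapa_onset_times"] = wrap(hapa_on_times),
      _["hapa_clear_times"] = wrap(hapa_clear_times));
}
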
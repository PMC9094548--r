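# shared fixtures: canonical test conditions and noise-free sensing

midpoint_settings <- function(...) {
  vent_settings(pip_target = 30, peep_setting = 5, respiratory_rate = 15,
                ie_ratio = "1:2", ...)
}

midpoint_config <- function(duration = NULL, n_cycles = NULL, seed = 1,
                            noise = FALSE, ...) {
  sim_config(settings = midpoint_settings(),
             lung = lung_params(20, 20),
             sensors = if (noise) sensor_model() else
               sensor_model(pressure_noise_sd = 0, flow_noise_sd = 0),
             duration = duration, n_cycles = n_cycles, seed = seed, ...)
}

pediatric_config <- function(n_cycles = 100, seed = 1, noise = TRUE, ...) {
  sim_config(settings = vent_settings(pip_target = 20, peep_setting = 5,
                                      respiratory_rate = 25, t_insp = 0.6),
             lung = lung_params(10, 25, residual_capacity = 400),
             sensors = if (noise) sensor_model() else
               sensor_model(pressure_noise_sd = 0, flow_noise_sd = 0),
             n_cycles = n_cycles, seed = seed, ...)
}

# square-wave analytic waveform: pressure P_hi for t_hi (INSPIRE), P_lo for
# t_lo (EXPIRE); expiratory flow f0 L/min held for t_flow then 0
square_breath_waveform <- function(n_cycles = 2, dt = 0.01, p_hi = 30,
                                   p_lo = 5, t_hi = 1, t_lo = 2,
                                   flow_lpm = 60, t_flow = 0.5) {
  t_cycle <- t_hi + t_lo
  tt <- seq(0, n_cycles * t_cycle, by = dt)
  tc <- tt %% t_cycle
  phase <- ifelse(tc < t_hi, 1L, 2L)
  p <- ifelse(phase == 1L, p_hi, p_lo)
  fout <- ifelse(phase == 2L & (tc - t_hi) < t_flow, flow_lpm, 0)
  waveform_record(tt, p, flow_in_Lpm = 0, flow_out_Lpm = fout,
                  volume_mL = 0, phase = phase)
}
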
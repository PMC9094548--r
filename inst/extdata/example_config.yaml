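# Example pcvsim configuration.
# Any omitted key falls back to the package default.

ventilator:
  pip_target: 30            # cmH2O, target peak inspiratory pressure
  peep_setting: 5           # cmH2O, mechanical PEEP valve setting
  respiratory_rate: 15      # breaths/min
  ie_ratio: "1:2"           # or give t_insp (seconds) instead
  flow_adjustment: 1        # scales the proportional gain (ramp speed)
  trigger_sensitivity: 1    # cmH2O below PEEP that triggers a breath
  # hapa_limit: 45          # cmH2O; default min(pip_target + 15, 60)
  fio2_set: 0.21

lung:
  compliance: 20            # mL/cmH2O
  resistance: 20            # cmH2O/(L/s)
  residual_capacity: 0      # mL (volume offset; does not alter pressures)

circuit:
  valve_max_flow: 85        # L/min at full drive
  expiratory_resistance: 10 # cmH2O/(L/s) of the open expiratory path
  tubing_compliance: 0      # mL/cmH2O, lumped
  valve_tau: 0.03           # s, proportional-valve response time constant

sensors:
  pressure_noise_sd: 0.1    # cmH2O
  flow_noise_sd: 0.5        # L/min
  pressure_gain: 1
  pressure_offset: 0
  flow_sensor_side: expiratory

gains:                      # see the methods vignette for the tuning
  kp: 0.13
  ki: 3
  kd: 0.004
  integral_clamp: 0.5
  deriv_tau: 0.12

events:                     # optional scheduled disturbances
  - kind: SPONTANEOUS_EFFORT
    onset: 10.5             # s
    duration: 0.4           # s
    magnitude: 3            # cmH2O effort depth

sim:
  dt_physics: 0.001         # s
  dt_control: 0.005         # s
  duration: 30              # s (or give n_cycles instead)
  seed: 1
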
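#' Ventilator settings
#'
#' Clinician-set variables for pressure-controlled ventilation. Ranges follow
#' the device's labeling: target PIP 15-60 cmH2O, PEEP 5-25 cmH2O,
#' respiratory rate 10-40 breaths/min, I:E ratio between 1:1 and 1:3. Exactly
#' one of `ie_ratio` (a string `"1:x"`) or `t_insp` (seconds) must be given;
#' the other is derived.
#'
#' @param pip_target target peak inspiratory pressure, cmH2O.
#' @param peep_setting mechanical PEEP-valve setting, cmH2O.
#' @param respiratory_rate mandatory breath rate, breaths/min.
#' @param ie_ratio inspiratory:expiratory time ratio as a string `"1:x"`
#'   with `x` a positive decimal, or `NULL` if `t_insp` is given.
#' @param t_insp inspiratory time in seconds, or `NULL` if `ie_ratio` is
#'   given.
#' @param flow_adjustment dimensionless factor (>= 0) scaling the
#'   proportional gain of the pressure controller; larger values shorten the
#'   pressure ramp.
#' @param trigger_sensitivity pressure drop below the PEEP setting (cmH2O)
#'   that counts as a patient inspiratory effort ("breath effort").
#' @param hapa_limit high-airway-pressure alarm limit, cmH2O. Defaults to
#'   `min(pip_target + 15, 60)`; hardware-style cap at 60 cmH2O.
#' @param fio2_set set inspired oxygen fraction (static channel).
#' @param validate if `FALSE`, skip the clinical range checks (research use,
#'   e.g. very slow test lungs); structural checks still apply.
#' @return an object of class `vent_settings`.
#' @examples
#' vent_settings(pip_target = 30, peep_setting = 5,
#'               respiratory_rate = 15, ie_ratio = "1:2")
#' @export
vent_settings <- function(pip_target = 30, peep_setting = 5,
                          respiratory_rate = 15, ie_ratio = "1:2",
                          t_insp = NULL, flow_adjustment = 1,
                          trigger_sensitivity = 1, hapa_limit = NULL,
                          fio2_set = 0.21, validate = TRUE) {
  if (!is.null(t_insp) && !missing(ie_ratio) && !is.null(ie_ratio))
    stop("give exactly one of `ie_ratio` or `t_insp`")
  if (!is.null(t_insp)) ie_ratio <- NULL
  stopifnot(is.numeric(pip_target), is.numeric(peep_setting),
            is.numeric(respiratory_rate), is.finite(pip_target),
            is.finite(peep_setting), is.finite(respiratory_rate))
  if (is.null(hapa_limit)) hapa_limit <- min(pip_target + 15, 60)
  s <- structure(list(
    pip_target = as.numeric(pip_target),
    peep_setting = as.numeric(peep_setting),
    respiratory_rate = as.numeric(respiratory_rate),
    ie_ratio = ie_ratio,
    t_insp = if (is.null(t_insp)) NULL else as.numeric(t_insp),
    flow_adjustment = as.numeric(flow_adjustment),
    trigger_sensitivity = as.numeric(trigger_sensitivity),
    hapa_limit = as.numeric(hapa_limit),
    fio2_set = as.numeric(fio2_set)
  ), class = "vent_settings")
  if (pip_target <= peep_setting)
    stop("pip_target must exceed peep_setting")
  if (s$flow_adjustment < 0) stop("flow_adjustment must be >= 0")
  if (s$trigger_sensitivity < 0) stop("trigger_sensitivity must be >= 0")
  tm <- breath_timing(s)  # validates I:E / t_insp consistency
  if (validate) {
    if (pip_target < 15 || pip_target > 60)
      stop("pip_target outside supported range 15-60 cmH2O")
    if (peep_setting < 5 || peep_setting > 25)
      stop("peep_setting outside supported range 5-25 cmH2O")
    if (respiratory_rate < 10 || respiratory_rate > 40)
      stop("respiratory_rate outside supported range 10-40 breaths/min")
    if (s$hapa_limit > 60)
      stop("hapa_limit cannot exceed 60 cmH2O")
    if (!is.null(ie_ratio)) {
      x <- parse_ie(ie_ratio)
      if (x < 1 || x > 3) stop("I:E ratio outside supported range 1:1-1:3")
    }
  }
  s
}

#' @export
print.vent_settings <- function(x, ...) {
  tm <- breath_timing(x)
  cat(sprintf(
    "<vent_settings> PIP %g / PEEP %g cmH2O, RR %g bpm, t_insp %.3g s (cycle %.3g s)\n",
    x$pip_target, x$peep_setting, x$respiratory_rate, tm["t_insp"],
    tm["t_cycle"]))
  invisible(x)
}

#' Parse an I:E ratio string
#'
#' @param ie_ratio string of the form `"1:x"` with `x` a positive decimal.
#' @return the numeric expiratory multiple `x`.
#' @keywords internal
parse_ie <- function(ie_ratio) {
  if (is.numeric(ie_ratio) && length(ie_ratio) == 1 && ie_ratio > 0)
    return(as.numeric(ie_ratio))
  m <- regmatches(ie_ratio,
                  regexec("^\\s*1\\s*:\\s*([0-9]*\\.?[0-9]+)\\s*$", ie_ratio))[[1]]
  if (length(m) != 2) stop("ie_ratio must have the form '1:x', got ", ie_ratio)
  x <- as.numeric(m[2])
  if (!is.finite(x) || x <= 0) stop("I:E expiratory multiple must be > 0")
  x
}

#' Breath-cycle timing
#'
#' Derive cycle, inspiratory and expiratory durations from the settings.
#' `t_cycle = 60/RR`; with an I:E ratio of 1:x, `t_insp = t_cycle/(1+x)`;
#' a directly given inspiratory time is used verbatim.
#'
#' @param settings a [vent_settings()] object.
#' @return named numeric vector `c(t_cycle, t_insp, t_exp)`, seconds.
#' @examples
#' breath_timing(vent_settings(respiratory_rate = 20, ie_ratio = "1:2"))
#' @export
breath_timing <- function(settings) {
  t_cycle <- 60 / settings$respiratory_rate
  if (!is.null(settings$t_insp)) {
    t_insp <- settings$t_insp
    if (t_insp >= t_cycle)
      stop("t_insp (", t_insp, " s) must be shorter than the cycle (",
           t_cycle, " s)")
  } else {
    x <- parse_ie(settings$ie_ratio)
    t_insp <- t_cycle / (1 + x)
  }
  c(t_cycle = t_cycle, t_insp = t_insp, t_exp = t_cycle - t_insp)
}

#' Test-lung parameters
#'
#' Linear single-compartment lung: alveolar pressure above PEEP baseline is
#' `volume / compliance`; flow through the airway obeys `dP = R * Q`. The
#' residual capacity (volume at zero distending pressure) is carried and
#' reported but does not alter the pressure-volume relation (linear model).
#'
#' @param compliance mL/cmH2O, > 0.
#' @param resistance cmH2O/(L/s), > 0.
#' @param residual_capacity mL, >= 0.
#' @return an object of class `lung_params`.
#' @export
lung_params <- function(compliance = 20, resistance = 20,
                        residual_capacity = 0) {
  stopifnot(is.finite(compliance), compliance > 0,
            is.finite(resistance), resistance > 0,
            is.finite(residual_capacity), residual_capacity >= 0)
  structure(list(compliance = as.numeric(compliance),
                 resistance = as.numeric(resistance),
                 residual_capacity = as.numeric(residual_capacity)),
            class = "lung_params")
}

#' Pneumatic-circuit parameters
#'
#' The inspiratory limb holds a current-driven proportional valve treated as
#' an ideal flow source (supply pressure far exceeds airway pressures) with a
#' first-order actuator lag; the expiratory limb holds a solenoid in series
#' with a mechanical PEEP valve modeled as an ideal threshold: zero flow at
#' or below the PEEP setting, linear in the overpressure above it.
#'
#' @param valve_max_flow proportional-valve flow at full drive, L/min, in
#'   (0, 100]. Default 85 (the largest flow exercised in validation).
#' @param expiratory_resistance cmH2O/(L/s) of the open expiratory path.
#' @param tubing_compliance lumped circuit compliance, mL/cmH2O; treated as
#'   additional parallel compliance (default 0).
#' @param valve_tau proportional-valve response time constant, s; 0 gives an
#'   instantaneous valve.
#' @param supply_pressure_ok static flag standing in for the 50 psi supply.
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(valve_max_flow = 85, expiratory_resistance = 10,
                           tubing_compliance = 0, valve_tau = 0.03,
                           supply_pressure_ok = TRUE) {
  stopifnot(is.finite(valve_max_flow), valve_max_flow > 0,
            valve_max_flow <= 100,
            is.finite(expiratory_resistance), expiratory_resistance > 0,
            is.finite(tubing_compliance), tubing_compliance >= 0,
            is.finite(valve_tau), valve_tau >= 0)
  structure(list(valve_max_flow = as.numeric(valve_max_flow),
                 expiratory_resistance = as.numeric(expiratory_resistance),
                 tubing_compliance = as.numeric(tubing_compliance),
                 valve_tau = as.numeric(valve_tau),
                 supply_pressure_ok = isTRUE(supply_pressure_ok)),
            class = "circuit_params")
}

#' Sensor model
#'
#' Affine sensor response with additive Gaussian noise:
#' `reading = gain * truth + offset + N(0, sd)`. One flow sensor is present;
#' its side of the circuit is configurable.
#'
#' @param pressure_noise_sd cmH2O.
#' @param flow_noise_sd L/min.
#' @param pressure_gain,pressure_offset affine miscalibration of the
#'   pressure channel (ideal: gain 1, offset 0).
#' @param sample_dt sensor sampling period, s.
#' @param flow_sensor_side `"expiratory"` (default; expiratory flow is the
#'   displayed quantity) or `"inspiratory"`.
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(pressure_noise_sd = 0.1, flow_noise_sd = 0.5,
                         pressure_gain = 1, pressure_offset = 0,
                         sample_dt = 0.005,
                         flow_sensor_side = c("expiratory", "inspiratory")) {
  flow_sensor_side <- match.arg(flow_sensor_side)
  stopifnot(pressure_noise_sd >= 0, flow_noise_sd >= 0, sample_dt > 0,
            is.finite(pressure_gain), is.finite(pressure_offset))
  structure(list(pressure_noise_sd = as.numeric(pressure_noise_sd),
                 flow_noise_sd = as.numeric(flow_noise_sd),
                 pressure_gain = as.numeric(pressure_gain),
                 pressure_offset = as.numeric(pressure_offset),
                 sample_dt = as.numeric(sample_dt),
                 flow_sensor_side = flow_sensor_side),
            class = "sensor_model")
}

#' PID gains
#'
#' Gains of the pressure controller, in valve-drive units per cmH2O of error
#' (the drive is clamped to \[0, 1\]). Defaults were tuned in simulation so
#' that the midpoint test condition (C = 20 mL/cmH2O, R = 20 cmH2O/L/s,
#' PIP 30, PEEP 5) reaches its target within a 300 ms ramp while the worst
#' peak-pressure overshoot across the C x R condition grid stays within the
#' validated 9% envelope; see the methods vignette for the procedure.
#'
#' @param kp proportional gain, drive per cmH2O.
#' @param ki integral gain, drive per cmH2O.s.
#' @param kd derivative gain, drive per cmH2O/s (acts on filtered error).
#' @param integral_clamp anti-windup clamp on the integral contribution, in
#'   drive units.
#' @param deriv_tau first-order filter time constant for the derivative
#'   term, s.
#' @return an object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 0.13, ki = 3, kd = 0.004,
                      integral_clamp = 0.5, deriv_tau = 0.12) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, integral_clamp >= 0, deriv_tau >= 0)
  structure(list(kp = as.numeric(kp), ki = as.numeric(ki),
                 kd = as.numeric(kd),
                 integral_clamp = as.numeric(integral_clamp),
                 deriv_tau = as.numeric(deriv_tau)),
            class = "pid_gains")
}
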
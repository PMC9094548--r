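#' Lung state
#'
#' Instantaneous state of the single-compartment lung. Volume is stored
#' internally in litres above residual capacity; pressures in cmH2O, flows
#' in L/s, time in seconds. Unit conversion to mL / L/min happens only at
#' the I/O boundary.
#'
#' @param volume_above_residual mL above residual capacity.
#' @param airway_pressure cmH2O at the airway opening.
#' @param flow_in,flow_out L/s.
#' @param time s.
#' @return an object of class `lung_state` (volume field in litres).
#' @export
lung_state <- function(volume_above_residual = 0, airway_pressure = 0,
                       flow_in = 0, flow_out = 0, time = 0) {
  v <- as.numeric(volume_above_residual) / 1000
  stopifnot(is.finite(v), v >= 0, is.finite(airway_pressure),
            is.finite(flow_in), is.finite(flow_out), is.finite(time))
  structure(list(volume = v, airway_pressure = as.numeric(airway_pressure),
                 flow_in = as.numeric(flow_in),
                 flow_out = as.numeric(flow_out), time = as.numeric(time)),
            class = "lung_state")
}

# alveolar (elastic recoil) pressure in cmH2O; compliance converted to
# L/cmH2O internally
alveolar_pressure <- function(state, params) {
  state$volume / (params$compliance / 1000)
}

#' Flow into the lung at a given applied airway pressure
#'
#' Linear R/C lung: `Q = (P_applied - V/C) / R`, positive into the lung.
#'
#' @param applied_pressure airway pressure, cmH2O.
#' @param state a [lung_state()].
#' @param params a [lung_params()].
#' @return flow in L/s (positive inflates the lung).
#' @examples
#' st <- lung_state(volume_above_residual = 0)
#' lung_flow(30, st, lung_params(compliance = 20, resistance = 20)) # 1.5 L/s
#' @export
lung_flow <- function(applied_pressure, state, params) {
  stopifnot(is.finite(applied_pressure))
  (applied_pressure - alveolar_pressure(state, params)) / params$resistance
}

#' Advance the lung state under a held airway pressure
#'
#' Integrates the one-compartment lung ODE `dV/dt = (P - V/C)/R` over `dt`.
#' The default explicit-Euler rule is accurate to well under 1% of `C * dP`
#' at the 1 ms physics step used by the simulator; `method = "exact"` uses
#' the closed-form exponential update instead.
#'
#' @param state a [lung_state()].
#' @param applied_pressure airway pressure held over the step, cmH2O.
#' @param dt step size, s, in (0, 0.01].
#' @param params a [lung_params()].
#' @param method `"euler"` (default) or `"exact"`.
#' @return the advanced `lung_state` (volume clamped at >= 0).
#' @export
step_lung <- function(state, applied_pressure, dt, params,
                      method = c("euler", "exact")) {
  method <- match.arg(method)
  if (!is.finite(dt) || dt <= 0 || dt > 0.01)
    stop("dt must lie in (0, 0.01] s")
  stopifnot(is.finite(applied_pressure))
  cl <- params$compliance / 1000        # L/cmH2O
  if (method == "euler") {
    q <- lung_flow(applied_pressure, state, params)
    v <- state$volume + q * dt
  } else {
    tau <- params$resistance * cl
    veq <- cl * applied_pressure
    v <- veq + (state$volume - veq) * exp(-dt / tau)
  }
  v <- max(v, 0)
  state$volume <- v
  state$airway_pressure <- applied_pressure
  state$flow_in <- max(lung_flow(applied_pressure, state, params), 0)
  state$flow_out <- max(-lung_flow(applied_pressure, state, params), 0)
  state$time <- state$time + dt
  state
}

#' Expiratory-limb flow through the solenoid + mechanical PEEP valve
#'
#' One-way threshold valve: zero flow when the solenoid is closed or the
#' airway pressure is at or below the PEEP setting; otherwise linear in the
#' overpressure, `Q = (P - PEEP) / R_exp`.
#'
#' @param airway_pressure cmH2O.
#' @param peep_setting mechanical PEEP-valve setting, cmH2O.
#' @param valve_open logical; solenoid state.
#' @param params a [circuit_params()].
#' @return expiratory flow, L/s (never negative).
#' @export
expiratory_flow <- function(airway_pressure, peep_setting, valve_open,
                            params) {
  stopifnot(is.finite(airway_pressure), is.finite(peep_setting))
  if (!isTRUE(valve_open) || airway_pressure <= peep_setting) return(0)
  (airway_pressure - peep_setting) / params$expiratory_resistance
}

#' Solve the airway-node pressure
#'
#' Quasi-static balance at the patient wye: valve inflow equals lung inflow
#' plus expiratory outflow. With the expiratory valve closed,
#' `P = P_alv + R * Q_in`; with it open the linear node equation is solved,
#' falling back to the closed-valve form when the solution sits below the
#' PEEP threshold (one-way valve).
#'
#' @param q_in inspiratory valve flow, L/s.
#' @param p_alv alveolar pressure (elastic recoil minus any patient effort),
#'   cmH2O.
#' @param exp_open logical; expiratory solenoid state.
#' @param peep_setting cmH2O.
#' @param lung a [lung_params()].
#' @param circuit a [circuit_params()].
#' @return airway pressure, cmH2O.
#' @keywords internal
airway_node_pressure <- function(q_in, p_alv, exp_open, peep_setting,
                                 lung, circuit) {
  R <- lung$resistance
  if (exp_open) {
    Re <- circuit$expiratory_resistance
    p <- (q_in + p_alv / R + peep_setting / Re) / (1 / R + 1 / Re)
    if (p > peep_setting) return(p)
  }
  p_alv + R * q_in
}

#' Read the sensors
#'
#' Produces one sensor frame from the true state:
#' `reading = gain * truth + offset + N(0, sd)`. Draws come from R's global
#' random-number stream, so a fixed seed reproduces frames exactly. The flow
#' reading reports the configured sensor side.
#'
#' @param state a [lung_state()].
#' @param model a [sensor_model()].
#' @param fio2 true oxygen fraction (static channel).
#' @return a one-row `data.frame`: `time`, `pressure_reading` (cmH2O),
#'   `flow_reading` (L/min), `fio2_reading`.
#' @export
read_sensors <- function(state, model, fio2 = 0.21) {
  p <- model$pressure_gain * state$airway_pressure + model$pressure_offset
  if (model$pressure_noise_sd > 0)
    p <- p + stats::rnorm(1, 0, model$pressure_noise_sd)
  q <- if (model$flow_sensor_side == "expiratory") state$flow_out else
    state$flow_in
  q <- q * 60                                   # L/s -> L/min at the boundary
  if (model$flow_noise_sd > 0)
    q <- q + stats::rnorm(1, 0, model$flow_noise_sd)
  data.frame(time = state$time, pressure_reading = p, flow_reading = q,
             fio2_reading = fio2)
}

#' Two-point / least-squares pressure-sensor calibration
#'
#' Fits the affine map `pressure = gain * raw + offset` from paired raw
#' readings and known pressures (ordinary least squares; exact for two
#' points). This is the in-software analogue of re-zeroing a drifted sensor
#' against a known pressure source.
#'
#' @param pairs a two-column matrix or data.frame: raw reading, known
#'   pressure (cmH2O). At least two pairs with distinct raw readings.
#' @return named numeric vector `c(gain, offset)`.
#' @examples
#' calibrate_pressure_sensor(rbind(c(0.5, 0), c(4.5, 100))) # gain 25, offset -12.5
#' @export
calibrate_pressure_sensor <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2) stop("need at least two calibration pairs")
  raw <- pairs[, 1]; known <- pairs[, 2]
  if (diff(range(raw)) == 0)
    stop("degenerate calibration input: all raw readings identical")
  fit <- stats::lm.fit(cbind(1, raw), known)
  c(gain = unname(fit$coefficients[2]), offset = unname(fit$coefficients[1]))
}
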
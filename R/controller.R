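#' Controller state
#'
#' Mutable state of the breath-cycle controller. Phase alternates strictly
#' INSPIRE -> EXPIRE -> INSPIRE; cycle position is tracked as an integer
#' control-tick count to keep long runs free of floating-point drift.
#'
#' @param phase `"INSPIRE"` or `"EXPIRE"`.
#' @param refractory_frac fraction of the expiratory time during which
#'   breath triggering is suppressed after the expiratory valve opens.
#' @param n_debounce consecutive control ticks a trigger or over-pressure
#'   condition must persist before it acts.
#' @return an object of class `controller_state`.
#' @export
controller_state <- function(phase = "INSPIRE", refractory_frac = 0.2,
                             n_debounce = 3) {
  stopifnot(phase %in% c("INSPIRE", "EXPIRE"),
            refractory_frac >= 0, refractory_frac < 1, n_debounce >= 1)
  structure(list(
    phase = phase,
    tick_in_cycle = 0L,
    cycle_index = 1L,
    integral_term = 0,
    error_filtered = 0,
    previous_error = 0,
    insp_start = TRUE,
    breath_trigger_armed = FALSE,
    override_active = FALSE,
    hapa_count = 0L,
    trigger_count = 0L,
    refractory_frac = refractory_frac,
    n_debounce = as.integer(n_debounce)
  ), class = "controller_state")
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf("<controller_state> cycle %d, phase %s, tick %d%s\n",
              x$cycle_index, x$phase, x$tick_in_cycle,
              if (x$override_active) " [OVERRIDE]" else ""))
  invisible(x)
}

#' One PID step of the pressure controller
#'
#' Computes the proportional-valve drive
#' `clamp(fa * kp * e + ki * int(e) + kd * de_f/dt, 0, 1)` with
#' `e = target - measured`. The flow-adjustment setting scales the
#' proportional gain only. The integral is frozen while the unclamped output
#' is saturated in the direction of the error (conditional anti-windup) and
#' its contribution is clamped to `integral_clamp` drive units; the
#' derivative acts on a first-order-filtered error.
#'
#' @param target,measured pressures, cmH2O.
#' @param gains a [pid_gains()].
#' @param cstate a [controller_state()].
#' @param dt control period, s.
#' @param flow_adjustment proportional-gain scale (>= 0).
#' @return `list(drive, state)` with `drive` in \[0, 1\] and the updated
#'   controller state.
#' @export
pid_step <- function(target, measured, gains, cstate, dt,
                     flow_adjustment = 1) {
  stopifnot(dt > 0)
  e <- target - measured
  if (cstate$insp_start) {
    cstate$error_filtered <- e
    cstate$previous_error <- e
    cstate$insp_start <- FALSE
  } else if (gains$deriv_tau > 0) {
    alpha <- dt / (dt + gains$deriv_tau)
    cstate$error_filtered <- cstate$error_filtered +
      alpha * (e - cstate$error_filtered)
  } else {
    cstate$error_filtered <- e
  }
  de <- (cstate$error_filtered - cstate$previous_error) / dt
  cstate$previous_error <- cstate$error_filtered

  icand <- cstate$integral_term + e * dt
  unsat <- flow_adjustment * gains$kp * e + gains$ki * icand + gains$kd * de
  if (!((unsat > 1 && e > 0) || (unsat < 0 && e < 0)))
    cstate$integral_term <- icand
  if (gains$ki > 0) {
    lim <- gains$integral_clamp / gains$ki
    cstate$integral_term <- min(max(cstate$integral_term, -lim), lim)
  }
  drive <- flow_adjustment * gains$kp * e +
    gains$ki * cstate$integral_term + gains$kd * de
  list(drive = min(max(drive, 0), 1), state = cstate)
}

# integer tick timing for a settings/dt pair
cycle_ticks <- function(settings, dt) {
  tm <- breath_timing(settings)
  n_cycle <- max(2L, as.integer(round(tm[["t_cycle"]] / dt)))
  n_insp <- min(max(1L, as.integer(round(tm[["t_insp"]] / dt))), n_cycle - 1L)
  c(n_cycle = n_cycle, n_insp = n_insp)
}

#' Detect a patient-initiated breath
#'
#' A spontaneous inspiratory effort during expiration pulls the airway
#' pressure transiently below PEEP. A breath is detected when, during the
#' EXPIRE phase and after a refractory window (a fixed fraction of the
#' expiratory time, guarding against valve-closure transients), the measured
#' pressure stays below `peep_setting - trigger_sensitivity` for
#' `n_debounce` consecutive control ticks. Detection re-synchronizes the
#' breath cycle (phase shift).
#'
#' @param pressure measured airway pressure this tick, cmH2O.
#' @param settings a [vent_settings()].
#' @param cstate a [controller_state()].
#' @param dt control period, s.
#' @return `list(triggered, state)`.
#' @export
detect_breath <- function(pressure, settings, cstate, dt) {
  nt <- cycle_ticks(settings, dt)
  refrac_ticks <- nt[["n_insp"]] +
    as.integer(ceiling(cstate$refractory_frac *
                         (nt[["n_cycle"]] - nt[["n_insp"]])))
  armed <- cstate$phase == "EXPIRE" && !cstate$override_active &&
    cstate$tick_in_cycle >= refrac_ticks
  cstate$breath_trigger_armed <- armed
  if (armed && pressure < settings$peep_setting - settings$trigger_sensitivity) {
    cstate$trigger_count <- cstate$trigger_count + 1L
  } else {
    cstate$trigger_count <- 0L
  }
  triggered <- cstate$trigger_count >= cstate$n_debounce
  if (triggered) cstate$trigger_count <- 0L
  list(triggered = triggered, state = cstate)
}

#' High-airway-pressure safety override
#'
#' When the measured pressure exceeds the alarm limit for `n_debounce`
#' consecutive ticks, the controller forces the proportional valve shut and
#' the expiratory valve open and raises the high-priority HAPA alarm. The
#' override holds until the pressure falls back below the limit; normal
#' cycling then resumes at the next cycle boundary.
#'
#' @param pressure measured airway pressure, cmH2O.
#' @param settings a [vent_settings()].
#' @param cstate a [controller_state()].
#' @return `list(state, hapa_active, cleared)`: `hapa_active` is TRUE on
#'   every tick the override (or its clearing tick) is in force.
#' @export
safety_override <- function(pressure, settings, cstate) {
  over <- pressure > settings$hapa_limit
  cleared <- FALSE
  if (over) {
    cstate$hapa_count <- cstate$hapa_count + 1L
    if (cstate$hapa_count >= cstate$n_debounce) cstate$override_active <- TRUE
  } else {
    cstate$hapa_count <- 0L
    if (cstate$override_active) {
      cstate$override_active <- FALSE
      cleared <- TRUE                     # pressure corrected this tick
    }
  }
  list(state = cstate,
       hapa_active = cstate$override_active || cleared,
       cleared = cleared)
}

#' One control tick
#'
#' The timed-cycle pressure controller: during INSPIRE the expiratory valve
#' is closed and the PID tracks the constant PIP target (the pressure ramp
#' and plateau emerge from that transient); at the inspiratory time the
#' phase switches to EXPIRE (drive 0, expiratory valve open); at the cycle
#' time — or earlier on a detected patient breath — a new cycle starts. The
#' safety override has absolute priority. If a detected breath and the
#' scheduled cycle end coincide on one tick, the schedule wins and the
#' breath is not flagged spontaneous.
#'
#' @param frame one-row sensor frame as returned by [read_sensors()].
#' @param settings a [vent_settings()].
#' @param gains a [pid_gains()].
#' @param cstate a [controller_state()].
#' @param dt control period, s.
#' @return `list(output, state, events)`: `output` has fields
#'   `valve_drive`, `expiratory_valve_open`, `new_cycle_started`,
#'   `spontaneous`, `safety_override`, `hapa_active`; `events` is a
#'   character vector (possibly empty) of `"HAPA"` / `"TRIGGER"` /
#'   `"HAPA_CLEAR"` markers.
#' @export
control_tick <- function(frame, settings, gains, cstate, dt) {
  p <- frame$pressure_reading
  events <- character()

  was_override <- cstate$override_active
  so <- safety_override(p, settings, cstate)
  cstate <- so$state
  if (cstate$override_active && !was_override) events <- c(events, "HAPA")
  if (so$cleared) events <- c(events, "HAPA_CLEAR")
  if (cstate$override_active) cstate$phase <- "EXPIRE"

  nt <- cycle_ticks(settings, dt)
  new_cycle <- FALSE
  spontaneous <- FALSE
  if (!cstate$override_active && !so$cleared &&
      cstate$tick_in_cycle >= nt[["n_cycle"]]) {
    new_cycle <- TRUE                       # scheduled start wins ties
  } else if (cstate$phase == "EXPIRE" && !cstate$override_active) {
    db <- detect_breath(p, settings, cstate, dt)
    cstate <- db$state
    if (db$triggered) {
      new_cycle <- TRUE
      spontaneous <- TRUE
      events <- c(events, "TRIGGER")
    }
  }
  if (new_cycle) {
    cstate$tick_in_cycle <- 0L
    cstate$phase <- "INSPIRE"
    cstate$cycle_index <- cstate$cycle_index + 1L
    cstate$insp_start <- TRUE
    cstate$trigger_count <- 0L
  }
  if (cstate$phase == "INSPIRE" && cstate$tick_in_cycle >= nt[["n_insp"]])
    cstate$phase <- "EXPIRE"

  if (cstate$override_active || so$cleared) {
    drive <- 0
    exp_open <- TRUE
  } else if (cstate$phase == "INSPIRE") {
    ps <- pid_step(settings$pip_target, p, gains, cstate, dt,
                   settings$flow_adjustment)
    cstate <- ps$state
    drive <- ps$drive
    exp_open <- FALSE
  } else {
    drive <- 0
    exp_open <- TRUE
  }
  cstate$tick_in_cycle <- cstate$tick_in_cycle + 1L

  list(output = list(valve_drive = drive,
                     expiratory_valve_open = exp_open,
                     new_cycle_started = new_cycle,
                     spontaneous = spontaneous,
                     safety_override = cstate$override_active,
                     hapa_active = so$hapa_active),
       state = cstate,
       events = events)
}
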
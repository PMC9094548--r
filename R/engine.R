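#' Scheduled event
#'
#' Events injected into the physics during a run. A `SPONTANEOUS_EFFORT`
#' models patient inspiratory muscle effort as a negative offset on the
#' alveolar pressure (producing the transient PEEP dip a triggered breath is
#' detected from); a `PRESSURE_TRANSIENT` adds a positive offset to the
#' airway pressure (e.g. an external squeeze producing an over-pressure
#' spike).
#'
#' @param kind `"SPONTANEOUS_EFFORT"` or `"PRESSURE_TRANSIENT"`.
#' @param onset start time, s (>= 0).
#' @param duration s (> 0).
#' @param magnitude cmH2O (effort depth or transient amplitude).
#' @return an object of class `event_spec`.
#' @export
event_spec <- function(kind = c("SPONTANEOUS_EFFORT", "PRESSURE_TRANSIENT"),
                       onset, duration, magnitude) {
  kind <- match.arg(kind)
  stopifnot(onset >= 0, duration > 0, is.finite(magnitude))
  structure(list(kind = kind, onset = as.numeric(onset),
                 duration = as.numeric(duration),
                 magnitude = as.numeric(magnitude)),
            class = "event_spec")
}

#' Apply an event to the physics inputs
#'
#' @param kind event kind (see [event_spec()]).
#' @param magnitude cmH2O.
#' @param inputs `list(alveolar_pressure, airway_offset)` — the effective
#'   alveolar pressure and the additive airway-pressure offset for the
#'   current physics step.
#' @return the modified `inputs` list.
#' @export
apply_event <- function(kind, magnitude, inputs) {
  if (kind == "SPONTANEOUS_EFFORT") {
    inputs$alveolar_pressure <- inputs$alveolar_pressure - magnitude
  } else if (kind == "PRESSURE_TRANSIENT") {
    inputs$airway_offset <- inputs$airway_offset + magnitude
  } else {
    stop("unknown event kind: ", kind)
  }
  inputs
}

#' Simulation configuration
#'
#' Bundles every input of a closed-loop run. Exactly one of `duration`
#' (seconds) or `n_cycles` (complete breath cycles) must be given.
#' `dt_control` must be an integer multiple of `dt_physics`.
#'
#' @param settings a [vent_settings()].
#' @param lung a [lung_params()].
#' @param circuit a [circuit_params()].
#' @param sensors a [sensor_model()].
#' @param gains a [pid_gains()].
#' @param events list of [event_spec()] objects.
#' @param dt_physics physics step, s.
#' @param dt_control control period, s.
#' @param duration run length in seconds, or `NULL`.
#' @param n_cycles run length in complete cycles, or `NULL`.
#' @param seed integer seed for all stochastic draws (sensor noise).
#' @param refractory_frac,n_debounce trigger/override debounce parameters
#'   (see [controller_state()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(settings = vent_settings(), lung = lung_params(),
                       circuit = circuit_params(), sensors = sensor_model(),
                       gains = pid_gains(), events = list(),
                       dt_physics = 0.001, dt_control = 0.005,
                       duration = NULL, n_cycles = NULL, seed = 1L,
                       refractory_frac = 0.2, n_debounce = 3L) {
  if (is.null(duration) == is.null(n_cycles))
    stop("give exactly one of `duration` or `n_cycles`")
  nsub <- dt_control / dt_physics
  if (abs(nsub - round(nsub)) > 1e-9 || nsub < 1)
    stop("dt_control must be a positive integer multiple of dt_physics")
  if (inherits(events, "event_spec")) events <- list(events)
  stopifnot(all(vapply(events, inherits, TRUE, "event_spec")))
  structure(list(settings = settings, lung = lung, circuit = circuit,
                 sensors = sensors, gains = gains, events = events,
                 dt_physics = as.numeric(dt_physics),
                 dt_control = as.numeric(dt_control),
                 duration = if (is.null(duration)) NULL else as.numeric(duration),
                 n_cycles = if (is.null(n_cycles)) NULL else as.integer(n_cycles),
                 seed = as.integer(seed),
                 refractory_frac = as.numeric(refractory_frac),
                 n_debounce = as.integer(n_debounce)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  len <- if (!is.null(x$duration)) sprintf("%g s", x$duration) else
    sprintf("%d cycles", x$n_cycles)
  cat(sprintf(
    "<sim_config> %s, dt_physics %g ms, dt_control %g ms, seed %d, %d event(s)\n",
    len, 1000 * x$dt_physics, 1000 * x$dt_control, x$seed, length(x$events)))
  print(x$settings)
  cat(sprintf("  lung: C %g mL/cmH2O, R %g cmH2O/(L/s)\n",
              x$lung$compliance, x$lung$resistance))
  invisible(x)
}

# flatten a sim_config for the compiled core; `state` carries across chunks
core_args <- function(config, state, stop_mode, n_ticks = 0,
                      n_cycles_target = 0, max_ticks) {
  s <- config$settings
  nt <- cycle_ticks(s, config$dt_control)
  refrac <- nt[["n_insp"]] + as.integer(
    ceiling(config$refractory_frac * (nt[["n_cycle"]] - nt[["n_insp"]])))
  ev <- config$events
  # effective compliance lumps the (small) tubing compliance in parallel
  comp_L <- (config$lung$compliance + config$circuit$tubing_compliance) / 1000
  list(dt_control = config$dt_control, dt_physics = config$dt_physics,
       n_sub = as.integer(round(config$dt_control / config$dt_physics)),
       n_cycle_ticks = nt[["n_cycle"]], n_insp_ticks = nt[["n_insp"]],
       refrac_ticks = refrac, n_debounce = config$n_debounce,
       pip_target = s$pip_target, peep_setting = s$peep_setting,
       trigger_sensitivity = s$trigger_sensitivity,
       hapa_limit = s$hapa_limit, flow_adjustment = s$flow_adjustment,
       kp = config$gains$kp, ki = config$gains$ki, kd = config$gains$kd,
       integral_clamp = config$gains$integral_clamp,
       deriv_tau = config$gains$deriv_tau,
       compliance_L = comp_L, resistance = config$lung$resistance,
       qmax_Ls = config$circuit$valve_max_flow / 60,
       exp_resistance = config$circuit$expiratory_resistance,
       valve_tau = config$circuit$valve_tau,
       pressure_gain = config$sensors$pressure_gain,
       pressure_offset = config$sensors$pressure_offset,
       pressure_noise_sd = config$sensors$pressure_noise_sd,
       ev_kind = as.integer(vapply(ev, function(e)
         if (e$kind == "SPONTANEOUS_EFFORT") 1L else 2L, 1L)),
       ev_onset = vapply(ev, function(e) e$onset, 1),
       ev_end = vapply(ev, function(e) e$onset + e$duration, 1),
       ev_magnitude = vapply(ev, function(e) e$magnitude, 1),
       stop_mode = as.integer(stop_mode), n_ticks = as.numeric(n_ticks),
       n_cycles_target = as.numeric(n_cycles_target),
       max_ticks = as.numeric(max_ticks), state = state)
}

# initial physics/controller state: lung at PEEP equilibrium
initial_core_state <- function(config) {
  comp_L <- (config$lung$compliance + config$circuit$tubing_compliance) / 1000
  list(volume = comp_L * config$settings$peep_setting, qvalve = 0,
       time = 0, tick_in_cycle = 0L, cycle_index = 1, phase = 1L,
       integral = 0, error_filtered = 0, previous_error = 0,
       insp_start = TRUE, override_active = FALSE, hapa_count = 0L,
       trigger_count = 0L,
       last_paw = config$settings$peep_setting)
}

waveform_colnames <- c("time_s", "pressure_cmH2O", "flow_in_Lpm",
                       "flow_out_Lpm", "volume_mL", "phase", "valve_drive",
                       "exp_valve_open", "alarm_mask")

core_to_waveform <- function(res, config) {
  n <- as.integer(res$n_recorded)
  m <- res$waveform[seq_len(n), , drop = FALSE]
  wf <- data.frame(time_s = m[, 1], pressure_cmH2O = m[, 2],
                   flow_in_Lpm = m[, 3], flow_out_Lpm = m[, 4],
                   volume_mL = m[, 5], phase = as.integer(m[, 6]),
                   valve_drive = m[, 7],
                   exp_valve_open = as.integer(m[, 8]),
                   alarm_mask = as.integer(m[, 9]) * alarm_bit("HIGH_PRESSURE"))
  attr(wf, "dt") <- config$dt_control
  attr(wf, "new_cycle") <- as.integer(m[, 10])
  class(wf) <- c("waveform_record", "data.frame")
  wf
}

#' Run a closed-loop simulation
#'
#' Steps the physics at `dt_physics` and the controller at `dt_control`,
#' sampling the waveform at the control rate, then segments the record into
#' breaths, computes per-breath metrics and evaluates the alarm rules.
#' Identical configuration (including seed) gives identical output.
#'
#' @param config a [sim_config()].
#' @param engine `"compiled"` (C++ core, default) or `"r"` (pure-R
#'   reference implementation of the same loop; slower, used for
#'   cross-validation).
#' @param rules alarm rule set, default [alarm_rules()] for the settings.
#' @return an object of class `sim_result`: list with `waveform`
#'   (data.frame, one row per control tick: `time_s`, `pressure_cmH2O`
#'   (sensed), `flow_in_Lpm`, `flow_out_Lpm`, `volume_mL` (above residual
#'   capacity), `phase` (1 INSPIRE / 2 EXPIRE), `valve_drive`,
#'   `exp_valve_open`, `alarm_mask`), `breaths` (per-cycle metrics, see
#'   [breath_metrics()]), `alarms` (episode log), `events` (trigger/override
#'   times), and the `config`.
#' @examples
#' cfg <- sim_config(vent_settings(pip_target = 30, peep_setting = 5,
#'                                 respiratory_rate = 15, ie_ratio = "1:2"),
#'                   lung_params(20, 20), duration = 10, seed = 1)
#' res <- run_simulation(cfg)
#' head(res$breaths)
#' @export
run_simulation <- function(config, engine = c("compiled", "r"),
                           rules = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(rules)) rules <- alarm_rules(config$settings)
  set.seed(config$seed)
  tm <- breath_timing(config$settings)
  if (!is.null(config$duration)) {
    stop_mode <- 1L
    n_ticks <- as.integer(round(config$duration / config$dt_control))
    max_ticks <- n_ticks
    n_target <- 0
  } else {
    stop_mode <- 2L
    n_ticks <- 0
    n_target <- config$n_cycles
    max_ticks <- ceiling((n_target + 2) * tm[["t_cycle"]] / config$dt_control *
                           1.5) + 1000
  }
  st <- initial_core_state(config)
  args <- core_args(config, st, stop_mode, n_ticks, n_target, max_ticks)
  res <- if (engine == "compiled") sim_core(args) else sim_core_r(args)
  if (isTRUE(res$blew_up))
    stop("simulation diverged to non-finite state at t = ",
         signif(res$state$time, 6), " s")
  wf <- core_to_waveform(res, config)
  breaths <- breath_table(wf, config$settings)
  alarms <- alarm_episodes(wf, breaths, rules, config$settings)
  structure(list(waveform = wf, breaths = breaths, alarms = alarms,
                 events = list(trigger_times = res$trigger_times,
                               hapa_onset_times = res$hapa_onset_times,
                               hapa_clear_times = res$hapa_clear_times),
                 config = config, final_state = res$state),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d control ticks, %d complete breaths, %d alarm episode(s)\n",
              nrow(x$waveform), nrow(x$breaths), nrow(x$alarms)))
  if (nrow(x$breaths) > 0) {
    a <- aggregate_metrics(x$breaths)
    print(a, row.names = FALSE)
  }
  invisible(x)
}

# Pure-R engine: the same loop as sim_core.cpp built from the exported
# module operations. Used to cross-validate the compiled core.
sim_core_r <- function(args) {
  settings <- list(pip_target = args$pip_target,
                   peep_setting = args$peep_setting,
                   trigger_sensitivity = args$trigger_sensitivity,
                   hapa_limit = args$hapa_limit,
                   flow_adjustment = args$flow_adjustment)
  gains <- pid_gains(args$kp, args$ki, args$kd, args$integral_clamp,
                     args$deriv_tau)
  lung <- list(resistance = args$resistance)
  circuit <- list(expiratory_resistance = args$exp_resistance)
  dtc <- args$dt_control; dtp <- args$dt_physics; nsub <- args$n_sub
  C <- args$compliance_L; R <- args$resistance
  qmax <- args$qmax_Ls; Re <- args$exp_resistance; vtau <- args$valve_tau
  st <- args$state
  V <- st$volume; qvalve <- st$qvalve; t <- st$time; last_paw <- st$last_paw

  cs <- controller_state(phase = if (st$phase == 1) "INSPIRE" else "EXPIRE",
                         n_debounce = args$n_debounce)
  cs$tick_in_cycle <- as.integer(st$tick_in_cycle)
  cs$cycle_index <- as.integer(st$cycle_index)
  cs$integral_term <- st$integral
  cs$error_filtered <- st$error_filtered
  cs$previous_error <- st$previous_error
  cs$insp_start <- st$insp_start
  cs$override_active <- st$override_active
  cs$hapa_count <- as.integer(st$hapa_count)
  cs$trigger_count <- as.integer(st$trigger_count)

  nmax <- as.integer(args$max_ticks)
  wf <- matrix(0, nmax, 10)
  trig_times <- numeric(); hapa_on <- numeric(); hapa_clear <- numeric()
  rec <- 0L
  blew_up <- FALSE
  alpha <- if (args$deriv_tau > 0) dtc / (dtc + args$deriv_tau) else 1

  # mirror cycle_ticks()/refractory arithmetic via explicit tick counts
  tick_ctrl <- list(n_cycle = args$n_cycle_ticks, n_insp = args$n_insp_ticks,
                    refrac = args$refrac_ticks)

  event_inputs <- function(tt) {
    inputs <- list(alveolar_pressure = V / C, airway_offset = 0)
    ks <- args$ev_kind
    for (i in seq_along(ks)) {
      if (tt >= args$ev_onset[i] && tt < args$ev_end[i]) {
        kind <- if (ks[i] == 1L) "SPONTANEOUS_EFFORT" else "PRESSURE_TRANSIENT"
        inputs <- apply_event(kind, args$ev_magnitude[i], inputs)
      }
    }
    inputs
  }

  k <- 0L
  repeat {
    if (args$stop_mode == 1L && k >= args$n_ticks) break
    if (rec >= nmax) break

    p_meas <- args$pressure_gain * last_paw + args$pressure_offset
    if (args$pressure_noise_sd > 0)
      p_meas <- p_meas + stats::rnorm(1, 0, args$pressure_noise_sd)

    was_override <- cs$override_active
    so <- safety_override(p_meas, settings, cs)
    cs <- so$state
    if (cs$override_active && !was_override) hapa_on <- c(hapa_on, t)
    if (so$cleared) hapa_clear <- c(hapa_clear, t)
    if (cs$override_active) cs$phase <- "EXPIRE"

    new_cycle <- 0L
    if (!cs$override_active && !so$cleared &&
        cs$tick_in_cycle >= tick_ctrl$n_cycle) {
      new_cycle <- 1L
    } else if (cs$phase == "EXPIRE" && !cs$override_active) {
      armed <- cs$tick_in_cycle >= tick_ctrl$refrac
      if (armed &&
          p_meas < settings$peep_setting - settings$trigger_sensitivity) {
        cs$trigger_count <- cs$trigger_count + 1L
      } else cs$trigger_count <- 0L
      if (cs$trigger_count >= cs$n_debounce) {
        cs$trigger_count <- 0L
        new_cycle <- 2L
        trig_times <- c(trig_times, t)
      }
    }
    if (new_cycle > 0L) {
      cs$tick_in_cycle <- 0L
      cs$phase <- "INSPIRE"
      cs$cycle_index <- cs$cycle_index + 1L
      cs$insp_start <- TRUE
      cs$trigger_count <- 0L
    }
    if (cs$phase == "INSPIRE" && cs$tick_in_cycle >= tick_ctrl$n_insp)
      cs$phase <- "EXPIRE"

    if (cs$override_active || so$cleared) {
      drive <- 0; exp_open <- TRUE
    } else if (cs$phase == "INSPIRE") {
      ps <- pid_step(settings$pip_target, p_meas, gains, cs, dtc,
                     settings$flow_adjustment)
      cs <- ps$state
      drive <- ps$drive
      exp_open <- FALSE
    } else {
      drive <- 0; exp_open <- TRUE
    }
    cs$tick_in_cycle <- cs$tick_in_cycle + 1L

    inp <- event_inputs(t)
    paw <- airway_node_pressure(qvalve, inp$alveolar_pressure, exp_open,
                                settings$peep_setting, lung, circuit) +
      inp$airway_offset
    qexp <- if (exp_open && paw > settings$peep_setting)
      (paw - settings$peep_setting) / Re else 0
    rec <- rec + 1L
    wf[rec, ] <- c(t, p_meas, qvalve * 60, qexp * 60, V * 1000,
                   if (cs$phase == "INSPIRE") 1 else 2, drive,
                   as.numeric(exp_open),
                   as.numeric(cs$override_active || so$cleared), new_cycle)
    stop_after <- args$stop_mode == 2L && new_cycle > 0L &&
      cs$cycle_index > args$n_cycles_target

    qcmd <- drive * qmax
    for (j in seq_len(nsub) - 1L) {
      tt <- t + j * dtp
      qvalve <- if (vtau > 0) qvalve + (dtp / vtau) * (qcmd - qvalve) else qcmd
      inp <- event_inputs(tt)
      paw <- airway_node_pressure(qvalve, inp$alveolar_pressure, exp_open,
                                  settings$peep_setting, lung, circuit) +
        inp$airway_offset
      qlung <- (paw - inp$alveolar_pressure) / R
      V <- max(V + qlung * dtp, 0)
      last_paw <- paw
    }
    t <- t + dtc
    if (!is.finite(V) || !is.finite(last_paw)) { blew_up <- TRUE; break }
    if (stop_after) break
    k <- k + 1L
  }

  list(waveform = wf, n_recorded = rec,
       state = list(volume = V, qvalve = qvalve, time = t,
                    tick_in_cycle = cs$tick_in_cycle,
                    cycle_index = cs$cycle_index,
                    phase = if (cs$phase == "INSPIRE") 1L else 2L,
                    integral = cs$integral_term,
                    error_filtered = cs$error_filtered,
                    previous_error = cs$previous_error,
                    insp_start = cs$insp_start,
                    override_active = cs$override_active,
                    hapa_count = cs$hapa_count,
                    trigger_count = cs$trigger_count, last_paw = last_paw),
       blew_up = blew_up, trigger_times = trig_times,
       hapa_onset_times = hapa_on, hapa_clear_times = hapa_clear)
}
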
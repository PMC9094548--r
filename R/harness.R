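#' Default EUA-style test-condition grid
#'
#' The 3x3 product of test-lung compliance {5, 20, 50} mL/cmH2O and airway
#' resistance {5, 20, 50} cmH2O/(L/s), ventilated at PIP 30 / PEEP 5, RR 15,
#' I:E 1:2 (inside the validated 12-20 range), plus the pediatric condition
#' (C 10, R 25, PIP 20, PEEP 5, RR 25, inspiratory time 0.6 s, residual
#' capacity 400 mL) as a tenth labelled row. A custom grid with the same
#' columns can be loaded from CSV and passed to [run_grid()].
#'
#' @return data.frame, one row per condition: `label`, `compliance`,
#'   `resistance`, `residual_capacity`, `pip_target`, `peep_setting`,
#'   `respiratory_rate`, `ie_ratio`, `t_insp`.
#' @export
default_grid <- function() {
  cr <- expand.grid(compliance = c(5, 20, 50), resistance = c(5, 20, 50))
  adult <- data.frame(
    label = sprintf("C%g_R%g", cr$compliance, cr$resistance),
    compliance = cr$compliance, resistance = cr$resistance,
    residual_capacity = 0,
    pip_target = 30, peep_setting = 5, respiratory_rate = 15,
    ie_ratio = "1:2", t_insp = NA_real_, stringsAsFactors = FALSE)
  ped <- data.frame(
    label = "pediatric", compliance = 10, resistance = 25,
    residual_capacity = 400,
    pip_target = 20, peep_setting = 5, respiratory_rate = 25,
    ie_ratio = NA_character_, t_insp = 0.6, stringsAsFactors = FALSE)
  rbind(adult, ped)
}

condition_config <- function(condition, n_cycles, base_config = NULL,
                             seed = 1L) {
  if (is.null(base_config)) {
    settings <- vent_settings(
      pip_target = condition$pip_target,
      peep_setting = condition$peep_setting,
      respiratory_rate = condition$respiratory_rate,
      ie_ratio = if (!is.na(condition$ie_ratio)) condition$ie_ratio else NULL,
      t_insp = if (!is.null(condition$t_insp) && !is.na(condition$t_insp))
        condition$t_insp else NULL)
    sim_config(settings = settings,
               lung = lung_params(condition$compliance, condition$resistance,
                                  condition$residual_capacity),
               n_cycles = n_cycles, seed = seed)
  } else {
    cfg <- base_config
    cfg$settings <- vent_settings(
      pip_target = condition$pip_target,
      peep_setting = condition$peep_setting,
      respiratory_rate = condition$respiratory_rate,
      ie_ratio = if (!is.na(condition$ie_ratio)) condition$ie_ratio else NULL,
      t_insp = if (!is.null(condition$t_insp) && !is.na(condition$t_insp))
        condition$t_insp else NULL,
      flow_adjustment = base_config$settings$flow_adjustment,
      trigger_sensitivity = base_config$settings$trigger_sensitivity)
    cfg$lung <- lung_params(condition$compliance, condition$resistance,
                            condition$residual_capacity)
    cfg$duration <- NULL
    cfg$n_cycles <- as.integer(n_cycles)
    cfg$seed <- as.integer(seed)
    cfg
  }
}

#' Run one test condition
#'
#' Simulates `n_settle + n_measure` breath cycles and aggregates the
#' metrics over the measurement cycles only. Pass/fail defaults: measured
#' PIP within ±10% of target (the device's validated worst case was 9%),
#' VTE inside the 100-500 mL EUA window (adult conditions).
#'
#' @param condition one row of a condition grid (see [default_grid()]).
#' @param base_config optional [sim_config()] whose non-condition fields
#'   (gains, circuit, sensors, steps) are reused.
#' @param n_settle settle cycles excluded from aggregation (>= 0).
#' @param n_measure measurement cycles (>= 1).
#' @param seed run seed.
#' @param pip_tol_pct pass tolerance on PIP deviation, percent.
#' @param vte_window pass window on mean VTE, mL.
#' @return one-row data.frame: means of measured PIP / PEEP / VTE /
#'   inspired volume / rise time, `pip_dev_pct` =
#'   `100 |mean PIP - target| / target`, alarm count, pass flags, `failed`
#'   (TRUE when the simulation itself errored).
#' @export
run_condition <- function(condition, base_config = NULL, n_settle = 5,
                          n_measure = 20, seed = 1L, pip_tol_pct = 10,
                          vte_window = c(100, 500)) {
  if (n_measure < 1) stop("n_measure must be >= 1")
  if (n_settle < 0) stop("n_settle must be >= 0")
  cfg <- condition_config(condition, n_settle + n_measure, base_config,
                          seed)
  row <- data.frame(label = condition$label,
                    compliance = condition$compliance,
                    resistance = condition$resistance,
                    pip_target = condition$pip_target,
                    pip_mean = NA_real_, pip_dev_pct = NA_real_,
                    peep_mean = NA_real_, vte_mean = NA_real_,
                    inspired_mean = NA_real_, rise_time_mean = NA_real_,
                    alarm_count = NA_integer_, pass_pip = NA,
                    pass_vte = NA, failed = TRUE,
                    stringsAsFactors = FALSE)
  res <- tryCatch(run_simulation(cfg), error = function(e) e)
  if (inherits(res, "error")) {
    attr(row, "error") <- conditionMessage(res)
    return(row)
  }
  b <- res$breaths
  b <- b[b$cycle_index > n_settle, , drop = FALSE]
  row$pip_mean <- mean(b$measured_pip)
  row$pip_dev_pct <- 100 * abs(row$pip_mean - condition$pip_target) /
    condition$pip_target
  row$peep_mean <- mean(b$measured_peep)
  row$vte_mean <- mean(b$vte)
  row$inspired_mean <- mean(b$inspired_volume)
  row$rise_time_mean <- mean(b$rise_time, na.rm = TRUE)
  row$alarm_count <- nrow(res$alarms)
  row$pass_pip <- row$pip_dev_pct <= pip_tol_pct
  row$pass_vte <- row$vte_mean >= vte_window[1] &
    row$vte_mean <= vte_window[2]
  row$failed <- FALSE
  row
}

#' Run a condition grid
#'
#' @param grid condition grid (default [default_grid()]).
#' @param ... passed to [run_condition()].
#' @return performance report, one row per condition.
#' @export
run_grid <- function(grid = default_grid(), ...) {
  rows <- lapply(seq_len(nrow(grid)), function(i)
    run_condition(grid[i, , drop = FALSE], ...))
  do.call(rbind, rows)
}

#' Endurance run
#'
#' Long-run stability test at one condition: the compiled core is driven in
#' chunks so per-cycle metrics stream out while the waveform of each chunk
#' is discarded — memory use is bounded and independent of `n_cycles`. The
#' report includes the drift between the first and last 1000-cycle mean PIP
#' (or halves of the run when shorter).
#'
#' @param condition one row of a condition grid.
#' @param n_cycles total contiguous cycles requested (>= 1).
#' @param dt_physics,dt_control coarse steps make multi-day runs
#'   desk-feasible; the default 10 ms physics step trades ~integration
#'   accuracy documented in the vignette for speed.
#' @param chunk_cycles cycles simulated per streamed chunk.
#' @param seed run seed.
#' @return list: `cycles_completed`, `completed` (logical),
#'   `summary` (per-metric mean/sd over all cycles), `pip_drift_pct`,
#'   `alarm_episodes`, `alarms` (episode log), `first_mean_pip`,
#'   `last_mean_pip`.
#' @export
endurance_run <- function(condition, n_cycles, dt_physics = 0.01,
                          dt_control = 0.01, chunk_cycles = 500,
                          seed = 1L) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  cfg <- condition_config(condition, n_cycles = 1L, seed = seed)
  cfg$dt_physics <- dt_physics
  cfg$dt_control <- dt_control
  rules <- alarm_rules(cfg$settings)
  set.seed(cfg$seed)
  tm <- breath_timing(cfg$settings)
  st <- initial_core_state(cfg)
  done <- 0
  breaths_acc <- list()
  alarms_acc <- list()
  failed <- FALSE
  while (done < n_cycles) {
    take <- min(chunk_cycles, n_cycles - done)
    max_ticks <- ceiling((take + 2) * tm[["t_cycle"]] / dt_control * 1.5) +
      1000
    args <- core_args(cfg, st, stop_mode = 2L, n_ticks = 0,
                      n_cycles_target = st$cycle_index + take - 1,
                      max_ticks = max_ticks)
    res <- sim_core(args)
    if (isTRUE(res$blew_up)) failed <- TRUE
    wf <- core_to_waveform(res, cfg)
    b <- breath_table(wf, cfg$settings)
    if (nrow(b) > 0) {
      b$cycle_index <- b$cycle_index + done
      breaths_acc[[length(breaths_acc) + 1L]] <- b
      a <- alarm_episodes(wf, b, rules, cfg$settings)
      if (nrow(a) > 0) alarms_acc[[length(alarms_acc) + 1L]] <- a
      done <- done + nrow(b)
    }
    st <- res$state
    if (failed || nrow(b) == 0) break
  }
  breaths <- if (length(breaths_acc)) do.call(rbind, breaths_acc) else
    NULL
  alarms <- if (length(alarms_acc)) do.call(rbind, alarms_acc) else
    empty_alarm_log()
  nb <- if (is.null(breaths)) 0L else nrow(breaths)
  k <- min(1000L, max(1L, floor(nb / 2)))
  first_mean <- if (nb) mean(breaths$measured_pip[seq_len(k)]) else NA_real_
  last_mean <- if (nb) mean(breaths$measured_pip[(nb - k + 1L):nb]) else
    NA_real_
  list(cycles_completed = nb,
       completed = !failed && nb >= n_cycles,
       summary = if (nb) aggregate_metrics(breaths) else NULL,
       first_mean_pip = first_mean, last_mean_pip = last_mean,
       pip_drift_pct = if (nb) 100 * abs(last_mean - first_mean) /
         first_mean else NA_real_,
       alarm_episodes = nrow(alarms), alarms = alarms)
}
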
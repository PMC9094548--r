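# trapezoidal integral of y(t); t and y same length
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-n] + y[-1]) / 2)
}

#' Build a waveform record
#'
#' Assembles uniformly sampled channels into the standard waveform
#' data.frame used throughout the package. Channel units: time s, pressure
#' cmH2O, flows L/min, volume mL (above residual capacity); `phase` is 1
#' during inspiration and 2 during expiration.
#'
#' @param time_s,pressure_cmH2O,flow_in_Lpm,flow_out_Lpm,volume_mL,phase
#'   equal-length channels.
#' @param valve_drive,exp_valve_open,alarm_mask optional channels (default
#'   0).
#' @return a `waveform_record` data.frame.
#' @export
waveform_record <- function(time_s, pressure_cmH2O, flow_in_Lpm = 0,
                            flow_out_Lpm = 0, volume_mL = 0, phase,
                            valve_drive = 0, exp_valve_open = NULL,
                            alarm_mask = 0L) {
  n <- length(time_s)
  stopifnot(n >= 2, length(pressure_cmH2O) == n, length(phase) == n)
  dts <- diff(time_s)
  if (any(abs(dts - dts[1]) > 1e-9)) stop("sample times must be uniform")
  if (is.null(exp_valve_open)) exp_valve_open <- as.integer(phase == 2)
  wf <- data.frame(time_s = time_s, pressure_cmH2O = pressure_cmH2O,
                   flow_in_Lpm = rep_len(flow_in_Lpm, n),
                   flow_out_Lpm = rep_len(flow_out_Lpm, n),
                   volume_mL = rep_len(volume_mL, n),
                   phase = as.integer(phase),
                   valve_drive = rep_len(valve_drive, n),
                   exp_valve_open = rep_len(as.integer(exp_valve_open), n),
                   alarm_mask = rep_len(as.integer(alarm_mask), n))
  attr(wf, "dt") <- dts[1]
  class(wf) <- c("waveform_record", "data.frame")
  wf
}

#' Segment a waveform into breath cycles
#'
#' One segment per inspiration onset (phase channel entering INSPIRE); the
#' trailing incomplete cycle is dropped.
#'
#' @param record a waveform data.frame with a `phase` channel.
#' @return data.frame with columns `start`, `end` (row indices; `end` is
#'   the last row before the next onset).
#' @export
segment_breaths <- function(record) {
  if (is.null(record$phase) || nrow(record) == 0)
    stop("waveform record with a phase channel required")
  ph <- record$phase
  onset <- which(ph == 1L & c(TRUE, ph[-length(ph)] == 2L))
  if (length(onset) < 2)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = onset[-length(onset)], end = onset[-1] - 1L)
}

#' Per-breath metrics
#'
#' Derived quantities for one complete breath cycle: measured PIP (max
#' pressure during inspiration), measured PEEP (mean pressure over the final
#' fraction of expiration), expiratory tidal volume VTE (trapezoidal
#' integral of expiratory flow), inspired volume (integral of inspiratory
#' flow), rise time (first time from inspiration onset at which pressure
#' reaches `pip_target - pip_band`; `NA` if never) and mean airway pressure.
#'
#' @param segment slice of a waveform record covering exactly one cycle
#'   (rows from one inspiration onset up to the row before the next).
#' @param settings a [vent_settings()] (provides the PIP target and the
#'   nominal cycle time used to flag spontaneous breaths).
#' @param pip_band band below target that counts as "reached", cmH2O.
#' @param peep_frac final fraction of expiration averaged for PEEP.
#' @return one-row data.frame (`cycle_index` left `NA`; filled by
#'   [breath_table()]).
#' @export
breath_metrics <- function(segment, settings, pip_band = 1,
                           peep_frac = 0.1) {
  need <- c("time_s", "pressure_cmH2O", "flow_in_Lpm", "flow_out_Lpm",
            "phase")
  if (!all(need %in% names(segment)))
    stop("segment missing channels: ",
         paste(setdiff(need, names(segment)), collapse = ", "))
  insp <- segment$phase == 1L
  expi <- segment$phase == 2L
  if (!any(insp)) stop("segment has no inspiratory samples")
  t0 <- segment$time_s[1]
  p <- segment$pressure_cmH2O

  pip <- max(p[insp])
  peep <- if (any(expi)) {
    idx <- which(expi)
    k <- max(1L, ceiling(peep_frac * length(idx)))
    mean(p[utils::tail(idx, k)])
  } else NA_real_
  vte <- 1000 * trapz(segment$time_s[expi], segment$flow_out_Lpm[expi] / 60)
  vinsp <- 1000 * trapz(segment$time_s[insp], segment$flow_in_Lpm[insp] / 60)
  hit <- which(insp & p >= settings$pip_target - pip_band)
  rise <- if (length(hit)) segment$time_s[hit[1]] - t0 else NA_real_
  data.frame(cycle_index = NA_integer_, start_time = t0,
             measured_pip = pip, measured_peep = peep, vte = vte,
             inspired_volume = vinsp, rise_time = rise,
             mean_airway_pressure = mean(p), spontaneous = FALSE)
}

#' Breath table for a whole waveform
#'
#' Segments the record and computes [breath_metrics()] per cycle. A breath
#' is flagged spontaneous when the preceding cycle was cut short (its
#' duration fell more than ~one control tick below the scheduled cycle
#' time), i.e. the breath was started by a detected patient effort rather
#' than the schedule.
#'
#' @param record a waveform record.
#' @param settings a [vent_settings()].
#' @param ... passed to [breath_metrics()].
#' @return data.frame, one row per complete breath.
#' @export
breath_table <- function(record, settings, ...) {
  seg <- segment_breaths(record)
  if (nrow(seg) == 0) {
    return(data.frame(cycle_index = integer(), start_time = numeric(),
                      measured_pip = numeric(), measured_peep = numeric(),
                      vte = numeric(), inspired_volume = numeric(),
                      rise_time = numeric(),
                      mean_airway_pressure = numeric(),
                      spontaneous = logical()))
  }
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    s <- record[seg$start[i]:seg$end[i], , drop = FALSE]
    breath_metrics(s, settings, ...)
  })
  out <- do.call(rbind, rows)
  out$cycle_index <- seq_len(nrow(out))
  dt <- attr(record, "dt")
  if (is.null(dt)) dt <- stats::median(diff(record$time_s))
  t_cycle <- breath_timing(settings)[["t_cycle"]]
  if (nrow(out) > 1) {
    dur_prev <- diff(out$start_time)
    out$spontaneous <- c(FALSE, dur_prev < t_cycle - 1.5 * dt)
  }
  out
}

#' Compliance estimate from one breath
#'
#' Consistency diagnostic: `vte / (measured_pip - measured_peep)` in
#' mL/cmH2O. For a passive linear lung ventilated with long
#' inspiratory/expiratory phases this recovers the configured compliance.
#'
#' @param breath one row of a breath table.
#' @return estimated compliance, mL/cmH2O.
#' @export
estimate_compliance <- function(breath) {
  span <- breath$measured_pip - breath$measured_peep
  if (any(!is.finite(span)) || any(span <= 0))
    stop("pressure span must be positive")
  breath$vte / span
}

#' Mean and standard deviation of breath metrics
#'
#' Sample mean and sd per metric over a set of breath records; the sd of a
#' single record is 0.
#'
#' @param records breath table (>= 1 row).
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(records) {
  if (nrow(records) < 1) stop("need at least one breath record")
  cols <- c("measured_pip", "measured_peep", "vte", "inspired_volume",
            "rise_time", "mean_airway_pressure")
  cols <- intersect(cols, names(records))
  data.frame(
    metric = cols,
    mean = vapply(cols, function(cl) mean(records[[cl]], na.rm = TRUE), 1),
    sd = vapply(cols, function(cl) {
      x <- records[[cl]][is.finite(records[[cl]])]
      if (length(x) <= 1) 0 else stats::sd(x)
    }, 1),
    row.names = NULL)
}
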
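ALARM_TYPES <- c("HIGH_PRESSURE", "LOW_PRESSURE", "HYPERVENTILATION",
                 "HYPOVENTILATION", "OBSTRUCTION", "LOW_FIO2",
                 "PEEP_NOT_MET", "DISCONNECT_LEAK", "TECHNICAL")

PRIORITY_LEVELS <- c(low = 1L, medium = 2L, high = 3L)

# bit assigned to each alarm type in the waveform alarm mask
alarm_bit <- function(type) {
  bitwShiftL(1L, match(type, ALARM_TYPES) - 1L)
}

#' Default alarm rule set
#'
#' One rule per supported alarm type. Tick-rate rules (HIGH_PRESSURE,
#' LOW_FIO2, TECHNICAL) are evaluated on every sensor frame so detection
#' latency is bounded by `persistence * dt_control`; breath-rate rules are
#' evaluated once per completed breath. Defaults:
#' \itemize{
#'   \item HIGH_PRESSURE (high): pressure above the HAPA limit, 3 ticks.
#'   \item LOW_PRESSURE (medium): measured PIP below `pip_target - 5`, 3
#'     breaths.
#'   \item HYPOVENTILATION (medium): measured RR below half the set rate or
#'     VTE below 50% of its rolling median, 3 breaths.
#'   \item HYPERVENTILATION (medium): measured RR above 1.5x the set rate,
#'     3 breaths.
#'   \item OBSTRUCTION (medium): VTE below 25% of its rolling median while
#'     pressure is on target, 3 breaths.
#'   \item LOW_FIO2 (low): reading below `fio2_set - 0.05`, 3 ticks.
#'   \item PEEP_NOT_MET (medium): measured PEEP below `peep_setting - 3`,
#'     3 breaths.
#'   \item DISCONNECT_LEAK (high): inspiratory plateau below 5 cmH2O or
#'     inspired/expired volume mismatch above 25%, 3 breaths.
#'   \item TECHNICAL (high): non-finite sensor frame, 1 tick.
#' }
#' All thresholds/persistences are configurable by editing the returned
#' data.frame.
#'
#' @param settings a [vent_settings()] supplying the limits.
#' @param auto_acknowledge if `TRUE` (default) an episode clears as soon as
#'   its condition resolves; if `FALSE` episodes latch (safety-device
#'   convention) until acknowledged.
#' @return data.frame with columns `alarm_type`, `priority`, `threshold`,
#'   `persistence`, `scope` ("tick" or "breath") and attribute
#'   `auto_acknowledge`.
#' @export
alarm_rules <- function(settings, auto_acknowledge = TRUE) {
  r <- data.frame(
    alarm_type = c("HIGH_PRESSURE", "LOW_PRESSURE", "HYPERVENTILATION",
                   "HYPOVENTILATION", "OBSTRUCTION", "LOW_FIO2",
                   "PEEP_NOT_MET", "DISCONNECT_LEAK", "TECHNICAL"),
    priority = c("high", "medium", "medium", "medium", "medium", "low",
                 "medium", "high", "high"),
    threshold = c(settings$hapa_limit,        # cmH2O, upper
                  settings$pip_target - 5,    # cmH2O, lower on PIP
                  1.5 * settings$respiratory_rate,  # bpm, upper
                  0.5 * settings$respiratory_rate,  # bpm, lower (or VTE rule)
                  0.25,                       # fraction of rolling median VTE
                  settings$fio2_set - 0.05,   # fraction, lower
                  settings$peep_setting - 3,  # cmH2O, lower
                  0.25,                       # leak fraction
                  NA_real_),
    persistence = c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 1L),
    scope = c("tick", "breath", "breath", "breath", "breath", "tick",
              "breath", "breath", "tick"),
    stringsAsFactors = FALSE)
  attr(r, "auto_acknowledge") <- isTRUE(auto_acknowledge)
  r
}

validate_rules <- function(rules) {
  bad <- setdiff(rules$alarm_type, ALARM_TYPES)
  if (length(bad)) stop("unknown alarm type in rule set: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(rules$alarm_type))
    stop("each alarm type may appear at most once in a rule set")
  if (any(rules$persistence < 1)) stop("persistence must be >= 1")
  invisible(rules)
}

# rolling median of the previous values (window 10, needs >= 3); NA early
rolling_median_prev <- function(x, window = 10L, min_n = 3L) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window)
    if (i - lo >= min_n) out[i] <- stats::median(x[lo:(i - 1L)])
  }
  out
}

# per-breath condition matrix (breaths x rule types), given settings
breath_conditions <- function(breaths, rules, settings) {
  n <- nrow(breaths)
  get_thr <- function(type) rules$threshold[rules$alarm_type == type]
  dur <- c(diff(breaths$start_time),
           if (n > 0) breath_timing(settings)[["t_cycle"]] else numeric())
  rr_meas <- 60 / dur
  med_vte <- rolling_median_prev(breaths$vte)
  cond <- matrix(FALSE, n, length(ALARM_TYPES),
                 dimnames = list(NULL, ALARM_TYPES))
  has <- function(type) any(rules$alarm_type == type)
  if (n == 0) return(cond)
  if (has("LOW_PRESSURE"))
    cond[, "LOW_PRESSURE"] <- breaths$measured_pip < get_thr("LOW_PRESSURE")
  if (has("HYPERVENTILATION"))
    cond[, "HYPERVENTILATION"] <- rr_meas > get_thr("HYPERVENTILATION")
  if (has("HYPOVENTILATION"))
    cond[, "HYPOVENTILATION"] <- rr_meas < get_thr("HYPOVENTILATION") |
      (!is.na(med_vte) & breaths$vte < 0.5 * med_vte)
  if (has("OBSTRUCTION"))
    cond[, "OBSTRUCTION"] <- !is.na(med_vte) &
      breaths$vte < get_thr("OBSTRUCTION") * med_vte &
      abs(breaths$measured_pip - settings$pip_target) <=
        0.1 * settings$pip_target
  if (has("PEEP_NOT_MET"))
    cond[, "PEEP_NOT_MET"] <- breaths$measured_peep < get_thr("PEEP_NOT_MET")
  if (has("DISCONNECT_LEAK"))
    cond[, "DISCONNECT_LEAK"] <- breaths$measured_pip < 5 |
      (breaths$inspired_volume > 0 &
         (breaths$inspired_volume - breaths$vte) / breaths$inspired_volume >
           get_thr("DISCONNECT_LEAK"))
  cond
}

empty_alarm_log <- function() {
  data.frame(type = character(), priority = character(),
             onset_s = numeric(), clear_s = numeric(),
             observed = numeric(), limit = numeric(),
             stringsAsFactors = FALSE)
}

# episodes from a logical condition vector sampled at `times`:
# onset at the persistence-th consecutive TRUE, clear at the next FALSE
episodes_from_condition <- function(cond, times, persistence, observed,
                                    limit, type, priority) {
  out <- empty_alarm_log()
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!isTRUE(r$values[i]) || r$lengths[i] < persistence) next
    onset_idx <- starts[i] + persistence - 1L
    clear_idx <- ends[i] + 1L
    out <- rbind(out, data.frame(
      type = type, priority = priority,
      onset_s = times[onset_idx],
      clear_s = if (clear_idx <= length(times)) times[clear_idx] else
        NA_real_,
      observed = if (length(observed) > 1)
        max(observed[starts[i]:ends[i]], na.rm = TRUE) else observed,
      limit = limit, stringsAsFactors = FALSE))
  }
  out
}

# vectorized episode extraction over a full run (pipeline path; equivalent
# to ticking evaluate_alarms() over the run — equivalence is tested)
alarm_episodes <- function(waveform, breaths, rules, settings,
                           fio2_reading = NULL) {
  validate_rules(rules)
  out <- empty_alarm_log()
  t <- waveform$time_s
  has <- function(type) any(rules$alarm_type == type)
  rule <- function(type) rules[rules$alarm_type == type, ]
  if (has("HIGH_PRESSURE")) {
    r <- rule("HIGH_PRESSURE")
    out <- rbind(out, episodes_from_condition(
      waveform$pressure_cmH2O > r$threshold, t, r$persistence,
      waveform$pressure_cmH2O, r$threshold, "HIGH_PRESSURE", r$priority))
  }
  if (has("TECHNICAL")) {
    r <- rule("TECHNICAL")
    bad <- !stats::complete.cases(waveform) |
      !apply(is.finite(as.matrix(waveform[sapply(waveform, is.numeric)])),
             1, all)
    out <- rbind(out, episodes_from_condition(
      bad, t, r$persistence, NA_real_, NA_real_, "TECHNICAL", r$priority))
  }
  if (has("LOW_FIO2") && !is.null(fio2_reading)) {
    r <- rule("LOW_FIO2")
    out <- rbind(out, episodes_from_condition(
      fio2_reading < r$threshold, t, r$persistence, fio2_reading,
      r$threshold, "LOW_FIO2", r$priority))
  }
  if (nrow(breaths) > 0) {
    cond <- breath_conditions(breaths, rules, settings)
    bt <- breaths$start_time + c(diff(breaths$start_time),
                                 breath_timing(settings)[["t_cycle"]])
    for (type in intersect(rules$alarm_type[rules$scope == "breath"],
                           colnames(cond))) {
      r <- rule(type)
      obs <- switch(type,
                    LOW_PRESSURE = breaths$measured_pip,
                    PEEP_NOT_MET = breaths$measured_peep,
                    HYPERVENTILATION = ,
                    HYPOVENTILATION = 60 / c(diff(breaths$start_time),
                                             breath_timing(settings)[["t_cycle"]]),
                    breaths$vte)
      out <- rbind(out, episodes_from_condition(
        cond[, type], bt, r$persistence, obs, r$threshold, type,
        r$priority))
    }
  }
  out[order(out$onset_s), , drop = FALSE]
}

#' Alarm manager state
#'
#' @param rules an [alarm_rules()] data.frame.
#' @return fresh manager state for [evaluate_alarms()].
#' @export
alarm_manager <- function(rules) {
  validate_rules(rules)
  list(rules = rules,
       tick_counts = stats::setNames(integer(length(ALARM_TYPES)),
                                     ALARM_TYPES),
       breath_counts = stats::setNames(integer(length(ALARM_TYPES)),
                                       ALARM_TYPES),
       active = stats::setNames(logical(length(ALARM_TYPES)), ALARM_TYPES),
       onset = stats::setNames(rep(NA_real_, length(ALARM_TYPES)),
                               ALARM_TYPES),
       observed = stats::setNames(rep(NA_real_, length(ALARM_TYPES)),
                                  ALARM_TYPES),
       last_breath_seen = 0L,
       log = empty_alarm_log())
}

#' Evaluate alarms for one control tick
#'
#' The per-tick alarm engine: tick-scope rules are checked against the
#' current sensor frame; breath-scope rules are checked whenever new
#' completed breaths appear in `latest_breaths`. An episode opens once its
#' condition has persisted for the rule's persistence (ticks or breaths)
#' and is logged exactly once; with auto-acknowledge (rule-set attribute)
#' it clears when the condition resolves, otherwise it latches until
#' cleared AND acknowledged.
#'
#' @param frame one-row sensor frame (`time`, `pressure_reading`,
#'   `flow_reading`, `fio2_reading`), as from [read_sensors()].
#' @param latest_breaths breath table of completed breaths so far (ordered
#'   by cycle).
#' @param rules an [alarm_rules()] data.frame.
#' @param mstate manager state from [alarm_manager()] (or `NULL` to start).
#' @param settings a [vent_settings()].
#' @return `list(active, state)`: `active` is the alarm-event data.frame of
#'   currently active episodes (open `clear_s`).
#' @export
evaluate_alarms <- function(frame, latest_breaths, rules, mstate,
                            settings) {
  if (is.null(mstate)) mstate <- alarm_manager(rules)
  auto_ack <- !isFALSE(attr(rules, "auto_acknowledge"))
  tnow <- frame$time

  set_cond <- function(ms, type, cond, observed, limit, scope_count) {
    r <- rules[rules$alarm_type == type, ]
    if (nrow(r) == 0) return(ms)
    cnt <- ms[[scope_count]]
    cnt[type] <- if (isTRUE(cond)) cnt[type] + 1L else 0L
    ms[[scope_count]] <- cnt
    if (cnt[type] >= r$persistence && !ms$active[type]) {
      ms$active[type] <- TRUE
      ms$onset[type] <- tnow
      ms$observed[type] <- observed
    } else if (ms$active[type]) {
      if (isTRUE(cond))
        ms$observed[type] <- max(ms$observed[type], observed, na.rm = TRUE)
      if (!isTRUE(cond) && auto_ack) {
        ms$log <- rbind(ms$log, data.frame(
          type = type, priority = r$priority, onset_s = ms$onset[type],
          clear_s = tnow, observed = ms$observed[type],
          limit = r$threshold, stringsAsFactors = FALSE))
        ms$active[type] <- FALSE
        ms$onset[type] <- NA_real_
        ms$observed[type] <- NA_real_
      }
    }
    ms
  }

  p <- frame$pressure_reading
  mstate <- set_cond(mstate, "HIGH_PRESSURE",
                     p > rules$threshold[rules$alarm_type == "HIGH_PRESSURE"],
                     p, NA, "tick_counts")
  if (!is.null(frame$fio2_reading))
    mstate <- set_cond(mstate, "LOW_FIO2",
                       frame$fio2_reading <
                         rules$threshold[rules$alarm_type == "LOW_FIO2"],
                       frame$fio2_reading, NA, "tick_counts")
  mstate <- set_cond(mstate, "TECHNICAL",
                     !all(is.finite(unlist(frame[sapply(frame, is.numeric)]))),
                     NA_real_, NA, "tick_counts")

  nb <- if (is.null(latest_breaths)) 0L else nrow(latest_breaths)
  if (nb > mstate$last_breath_seen) {
    cond <- breath_conditions(latest_breaths, rules, settings)
    for (i in (mstate$last_breath_seen + 1L):nb) {
      for (type in rules$alarm_type[rules$scope == "breath"]) {
        obs <- switch(type,
                      LOW_PRESSURE = latest_breaths$measured_pip[i],
                      PEEP_NOT_MET = latest_breaths$measured_peep[i],
                      latest_breaths$vte[i])
        mstate <- set_cond(mstate, type, cond[i, type], obs, NA,
                           "breath_counts")
      }
    }
    mstate$last_breath_seen <- nb
  }

  act <- which(mstate$active)
  active <- if (length(act)) data.frame(
    type = names(mstate$active)[act],
    priority = rules$priority[match(names(mstate$active)[act],
                                    rules$alarm_type)],
    onset_s = unname(mstate$onset[act]),
    clear_s = NA_real_,
    observed = unname(mstate$observed[act]),
    limit = rules$threshold[match(names(mstate$active)[act],
                                  rules$alarm_type)],
    stringsAsFactors = FALSE) else empty_alarm_log()
  list(active = active, state = mstate)
}

#' Highest priority among active alarm events
#'
#' @param active alarm-event data.frame (possibly empty).
#' @return `"high"`, `"medium"`, `"low"`, or `NA_character_` when no alarm
#'   is active.
#' @export
highest_priority <- function(active) {
  if (is.null(active) || nrow(active) == 0) return(NA_character_)
  names(PRIORITY_LEVELS)[max(PRIORITY_LEVELS[active$priority])]
}
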
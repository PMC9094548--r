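test_that("sim_config enforces its structural invariants", {
  expect_error(sim_config(duration = 10, n_cycles = 5), "exactly one")
  expect_error(sim_config(), "exactly one")
  expect_error(sim_config(duration = 10, dt_physics = 0.002,
                          dt_control = 0.005), "integer multiple")
  expect_error(sim_config(duration = 10,
                          events = list(event_spec("PRESSURE_TRANSIENT",
                                                   -1, 1, 5))))
})

test_that("apply_event modifies exactly the intended physics input", {
  inputs <- list(alveolar_pressure = 10, airway_offset = 0)
  expect_identical(apply_event("SPONTANEOUS_EFFORT", 3, inputs),
                   list(alveolar_pressure = 7, airway_offset = 0))
  expect_identical(apply_event("PRESSURE_TRANSIENT", 20, inputs),
                   list(alveolar_pressure = 10, airway_offset = 20))
  expect_error(apply_event("NOPE", 1, inputs), "unknown event kind")
})

test_that("identical config and seed reproduce the run bit-identically", {
  cfg <- midpoint_config(duration = 10, noise = TRUE)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$waveform, b$waveform)
  expect_identical(a$breaths, b$breaths)
  # a different seed changes the sensed pressure
  cfg2 <- midpoint_config(duration = 10, seed = 2, noise = TRUE)
  c2 <- run_simulation(cfg2)
  expect_false(identical(a$waveform$pressure_cmH2O,
                         c2$waveform$pressure_cmH2O))
})

test_that("compiled and pure-R engines agree", {
  cfg <- midpoint_config(duration = 6, noise = TRUE)
  a <- run_simulation(cfg, engine = "compiled")
  b <- run_simulation(cfg, engine = "r")
  expect_equal(a$waveform, b$waveform, tolerance = 1e-9)
  expect_equal(a$breaths, b$breaths, tolerance = 1e-9)
})

test_that("closed-loop midpoint run tracks the pressure targets", {
  res <- run_simulation(midpoint_config(duration = 10))
  expect_gte(nrow(res$breaths), 2)
  wf <- res$waveform
  seg <- segment_breaths(wf)
  # plateau (last 20% of inspiration) within +-1 cmH2O of the 30 target
  s <- wf[seg$start[2]:seg$end[2], ]
  ins <- which(s$phase == 1)
  plateau <- mean(s$pressure_cmH2O[utils::tail(ins,
                                               ceiling(0.2 * length(ins)))])
  expect_lt(abs(plateau - 30), 1)
  # measured PEEP near the valve setting
  expect_lt(abs(res$breaths$measured_peep[2] - 5), 0.5)
})

test_that("halving the physics step changes VTE by less than 0.5%", {
  c1 <- midpoint_config(n_cycles = 6)
  c2 <- midpoint_config(n_cycles = 6)
  c2$dt_physics <- 0.0005
  v1 <- mean(run_simulation(c1)$breaths$vte[-(1:3)])
  v2 <- mean(run_simulation(c2)$breaths$vte[-(1:3)])
  expect_lt(abs(v1 - v2) / v1, 0.005)
})

test_that("mass is conserved over steady-state cycles", {
  res <- run_simulation(midpoint_config(n_cycles = 8))
  wf <- res$waveform
  seg <- segment_breaths(wf)
  for (i in 4:nrow(seg)) {
    s <- wf[seg$start[i]:seg$end[i], ]
    insp <- s$phase == 1
    vin <- 1000 * pcvsim:::trapz(s$time_s[insp], s$flow_in_Lpm[insp] / 60)
    vout <- 1000 * pcvsim:::trapz(s$time_s[!insp],
                                  s$flow_out_Lpm[!insp] / 60)
    dv <- s$volume_mL[nrow(s)] - s$volume_mL[1]
    tidal <- max(s$volume_mL) - min(s$volume_mL)
    expect_lt(abs((vin - vout) - dv), 0.005 * tidal)
  }
})

test_that("volume stays non-negative and drive within bounds everywhere", {
  res <- run_simulation(midpoint_config(duration = 20, noise = TRUE))
  wf <- res$waveform
  expect_true(all(wf$volume_mL >= 0))
  expect_true(all(wf$valve_drive >= 0 & wf$valve_drive <= 1))
  # expiratory valve and positive drive never commanded together
  expect_false(any(wf$exp_valve_open == 1 & wf$valve_drive > 0))
})

test_that("a spontaneous effort during PEEP triggers an early cycle", {
  cfg <- midpoint_config(duration = 30)
  cfg$events <- list(event_spec("SPONTANEOUS_EFFORT", onset = 15,
                                duration = 0.5, magnitude = 5))
  res <- run_simulation(cfg)
  expect_length(res$events$trigger_times, 1)
  expect_gte(res$events$trigger_times, 15)
  expect_lt(res$events$trigger_times, 15.6)
  expect_equal(sum(res$breaths$spontaneous), 1)
  # the airway pressure dipped more than the sensitivity below PEEP
  dip <- min(res$waveform$pressure_cmH2O[res$waveform$time_s >= 15 &
                                           res$waveform$time_s < 15.5])
  expect_lt(dip, 5 - 1)
  # segment boundaries follow the actual (shifted) cycle starts
  starts <- res$breaths$start_time
  expect_lt(max(diff(starts)[diff(starts) < 3.9]), 4)
})

test_that("no event means no spontaneous flags and no alarms", {
  res <- run_simulation(midpoint_config(duration = 30, noise = TRUE))
  expect_equal(sum(res$breaths$spontaneous), 0)
  expect_length(res$events$trigger_times, 0)
  expect_equal(nrow(res$alarms), 0)
})

test_that("a high-pressure transient raises HAPA and is corrected quickly", {
  cfg <- midpoint_config(duration = 30)
  cfg$events <- list(event_spec("PRESSURE_TRANSIENT", onset = 16.5,
                                duration = 0.2, magnitude = 20))
  res <- run_simulation(cfg)
  expect_equal(sum(res$alarms$type == "HIGH_PRESSURE"), 1)
  expect_equal(highest_priority(res$alarms), "high")
  wf <- res$waveform
  i_over <- which(wf$pressure_cmH2O > 45)[1]
  i_ok <- which(seq_len(nrow(wf)) > i_over & wf$pressure_cmH2O < 45 &
                  wf$exp_valve_open == 1 &
                  cummax(wf$alarm_mask > 0) >= 1)[1]
  expect_lt(wf$time_s[i_ok] - wf$time_s[i_over], 0.5)
  # override held: drive 0 and valve open on every over-limit tick after
  # detection
  det <- which(wf$alarm_mask > 0)
  expect_true(all(wf$valve_drive[det] == 0))
  expect_true(all(wf$exp_valve_open[det] == 1))
  # cycling resumes: later breaths back on target
  later <- res$breaths[res$breaths$start_time > 21, ]
  expect_lt(abs(mean(later$measured_pip) - 30), 3)
})

test_that("pediatric condition delivers the closed-form-bracketed volume", {
  res <- run_simulation(pediatric_config(n_cycles = 20, noise = FALSE))
  b <- res$breaths[res$breaths$cycle_index > 5, ]
  # C*(PIP-PEEP) = 150 mL asymptote; 0.6 s exponential bound ~136 mL
  expect_true(all(b$inspired_volume > 100 & b$inspired_volume < 150))
})

test_that("long-run PIP is stable at the midpoint condition", {
  res <- run_simulation(midpoint_config(n_cycles = 60))
  b <- res$breaths[res$breaths$cycle_index > 5, ]
  expect_lt(stats::sd(b$measured_pip), 0.5)
})

test_that("numeric blow-up is reported, not silently clipped", {
  cfg <- midpoint_config(duration = 5)
  cfg$sensors$pressure_offset <- NaN
  expect_error(run_simulation(cfg), "diverged|finite")
})
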
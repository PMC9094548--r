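test_that("breath timing splits the cycle per RR and I:E / t_insp", {
  # the pediatric condition: RR 25, t_insp 0.6 -> cycle 2.4, t_exp 1.8
  tm <- breath_timing(vent_settings(20, 5, 25, t_insp = 0.6))
  expect_equal(unname(tm), c(2.4, 0.6, 1.8))
  tm <- breath_timing(vent_settings(30, 5, 10, "1:1"))
  expect_equal(unname(tm), c(6, 3, 3))
  tm <- breath_timing(vent_settings(30, 5, 20, "1:2"))
  expect_equal(unname(tm), c(3, 1, 2))
  expect_error(vent_settings(30, 5, 20, t_insp = 3.5), "t_insp")
  expect_error(parse_ie("2:1"))
  expect_error(vent_settings(30, 5, 15, "1:4"), "I:E")
})

test_that("settings validation enforces the labeled ranges", {
  expect_error(vent_settings(pip_target = 10), "pip_target")
  expect_error(vent_settings(peep_setting = 30), "peep_setting")
  expect_error(vent_settings(respiratory_rate = 50), "respiratory_rate")
  expect_error(vent_settings(pip_target = 20, peep_setting = 20), "exceed")
  expect_silent(vent_settings(pip_target = 10, peep_setting = 4,
                              respiratory_rate = 5, ie_ratio = "1:1",
                              validate = FALSE))
  # default alarm limit: pip + 15, capped at 60
  expect_equal(vent_settings(pip_target = 30)$hapa_limit, 45)
  expect_equal(vent_settings(pip_target = 55)$hapa_limit, 60)
})

test_that("pid_step is exactly proportional with ki = kd = 0", {
  g <- pid_gains(kp = 0.1, ki = 0, kd = 0)
  cs <- controller_state()
  expect_equal(pid_step(30, 30, g, cs, 0.005)$drive, 0)
  expect_equal(pid_step(30, 25, g, cs, 0.005)$drive, 0.5)
  # flow adjustment scales the proportional gain; output clamps at 1
  expect_equal(pid_step(30, 25, g, cs, 0.005, flow_adjustment = 2)$drive, 1)
  # doubling the error doubles the unclamped drive
  d1 <- pid_step(30, 28, g, cs, 0.005)$drive
  d2 <- pid_step(30, 26, g, cs, 0.005)$drive
  expect_equal(d2, 2 * d1)
  # linear in flow_adjustment below the clamp
  d <- pid_step(30, 28, g, cs, 0.005, flow_adjustment = 1.5)$drive
  expect_equal(d, 1.5 * d1)
})

test_that("pid integral freezes while saturated and respects its clamp", {
  g <- pid_gains(kp = 0.5, ki = 1, kd = 0, integral_clamp = 0.2)
  cs <- controller_state()
  # large error: output saturated, integral must not wind up
  r <- pid_step(30, 0, g, cs, 0.005)
  expect_equal(r$drive, 1)
  expect_equal(r$state$integral_term, 0)
  # small error: integral accumulates but ki*I stays within the clamp
  g2 <- pid_gains(kp = 0, ki = 10, kd = 0, integral_clamp = 0.2)
  cs <- controller_state()
  for (i in 1:200) {
    r <- pid_step(30, 29, g2, cs, 0.005)
    cs <- r$state
  }
  expect_lte(g2$ki * cs$integral_term, 0.2 + 1e-12)
  expect_equal(r$drive, 0.2)
})

test_that("drive is always within [0, 1]", {
  g <- pid_gains(kp = 0.2, ki = 0.5, kd = 0.01)
  cs <- controller_state()
  set.seed(1)
  for (i in 1:300) {
    r <- pid_step(30, runif(1, -20, 80), g, cs, 0.005)
    cs <- r$state
    expect_gte(r$drive, 0)
    expect_lte(r$drive, 1)
  }
})

test_that("breath detection requires phase, refractory window and debounce", {
  s <- midpoint_settings(trigger_sensitivity = 1)
  dt <- 0.005
  nt <- pcvsim:::cycle_ticks(s, dt)      # cycle 800, insp 267 ticks
  low <- s$peep_setting - 3              # clear dip below PEEP - sensitivity
  # during INSPIRE: never triggers
  cs <- controller_state(phase = "INSPIRE")
  cs$tick_in_cycle <- 10L
  for (i in 1:10) {
    r <- detect_breath(low, s, cs, dt); cs <- r$state
    expect_false(r$triggered)
  }
  # during EXPIRE before the refractory window has elapsed: never triggers
  cs <- controller_state(phase = "EXPIRE")
  cs$tick_in_cycle <- nt[["n_insp"]] + 1L
  r <- detect_breath(low, s, cs, dt)
  expect_false(r$triggered)
  expect_false(r$state$breath_trigger_armed)
  # past refractory: needs n_debounce consecutive low ticks
  cs <- controller_state(phase = "EXPIRE")
  cs$tick_in_cycle <- nt[["n_cycle"]] - 50L
  r <- detect_breath(low, s, cs, dt); cs <- r$state
  expect_false(r$triggered)
  r <- detect_breath(low, s, cs, dt); cs <- r$state
  expect_false(r$triggered)
  r <- detect_breath(low, s, cs, dt); cs <- r$state
  expect_true(r$triggered)
  # flat pressure at PEEP never triggers
  cs <- controller_state(phase = "EXPIRE")
  cs$tick_in_cycle <- nt[["n_cycle"]] - 50L
  for (i in 1:20) {
    r <- detect_breath(s$peep_setting, s, cs, dt); cs <- r$state
    expect_false(r$triggered)
  }
  # a 2-tick dip interrupted by recovery does not trigger (debounce reset)
  cs <- controller_state(phase = "EXPIRE")
  cs$tick_in_cycle <- nt[["n_cycle"]] - 50L
  for (p in c(low, low, s$peep_setting, low, low)) {
    r <- detect_breath(p, s, cs, dt); cs <- r$state
    expect_false(r$triggered)
  }
})

test_that("safety override engages after debounce and clears below the limit", {
  s <- midpoint_settings()             # hapa_limit 45
  cs <- controller_state()
  r <- safety_override(40, s, cs); cs <- r$state
  expect_false(cs$override_active)
  for (i in 1:2) { r <- safety_override(50, s, cs); cs <- r$state }
  expect_false(cs$override_active)     # 2 ticks < debounce of 3
  r <- safety_override(50, s, cs); cs <- r$state
  expect_true(cs$override_active)
  expect_true(r$hapa_active)
  # stays active while above the limit
  r <- safety_override(46, s, cs); cs <- r$state
  expect_true(cs$override_active)
  # clears on first tick below the limit; that tick still reports active
  r <- safety_override(40, s, cs); cs <- r$state
  expect_false(cs$override_active)
  expect_true(r$hapa_active)
  expect_true(r$cleared)
  r <- safety_override(40, s, cs)
  expect_false(r$hapa_active)
})

test_that("control_tick drives the strict INSPIRE/EXPIRE alternation", {
  s <- midpoint_settings()
  g <- pid_gains()
  dt <- 0.005
  nt <- pcvsim:::cycle_ticks(s, dt)
  cs <- controller_state()
  frame <- function(p) data.frame(time = 0, pressure_reading = p,
                                  flow_reading = 0, fio2_reading = 0.21)
  phases <- character(nt[["n_cycle"]] + 1L)
  cycles <- integer(nt[["n_cycle"]] + 1L)
  for (i in seq_len(nt[["n_cycle"]] + 1L)) {
    r <- control_tick(frame(10), s, g, cs, dt)
    cs <- r$state
    phases[i] <- cs$phase
    cycles[i] <- cs$cycle_index
    if (cs$phase == "INSPIRE") expect_false(r$output$expiratory_valve_open)
    if (cs$phase == "EXPIRE") {
      expect_true(r$output$expiratory_valve_open)
      expect_equal(r$output$valve_drive, 0)
    }
  }
  # one phase change INSPIRE -> EXPIRE at n_insp, back at cycle end
  expect_equal(phases[nt[["n_insp"]]], "INSPIRE")
  expect_equal(phases[nt[["n_insp"]] + 1L], "EXPIRE")
  expect_equal(phases[nt[["n_cycle"]] + 1L], "INSPIRE")
  # cycle_index increments exactly once, at the scheduled boundary
  expect_equal(unique(cycles), c(1L, 2L))
  expect_equal(sum(diff(cycles)), 1L)
})

test_that("a PEEP dip during expiration re-synchronizes the cycle", {
  s <- midpoint_settings(trigger_sensitivity = 1)
  g <- pid_gains()
  dt <- 0.005
  nt <- pcvsim:::cycle_ticks(s, dt)
  cs <- controller_state()
  cs$phase <- "EXPIRE"
  cs$tick_in_cycle <- nt[["n_cycle"]] - 100L    # well past refractory
  frame <- function(p) data.frame(time = 0, pressure_reading = p,
                                  flow_reading = 0, fio2_reading = 0.21)
  started <- FALSE
  for (i in 1:5) {
    r <- control_tick(frame(2), s, g, cs, dt)
    cs <- r$state
    if (r$output$new_cycle_started) {
      started <- TRUE
      expect_true(r$output$spontaneous)
      expect_lt(i, nt[["n_cycle"]])             # before the schedule
      break
    }
  }
  expect_true(started)
  expect_equal(cs$phase, "INSPIRE")
})

test_that("scheduled cycle start wins a tie with a detected breath", {
  s <- midpoint_settings(trigger_sensitivity = 1)
  g <- pid_gains()
  dt <- 0.005
  nt <- pcvsim:::cycle_ticks(s, dt)
  cs <- controller_state()
  cs$phase <- "EXPIRE"
  cs$tick_in_cycle <- nt[["n_cycle"]] - 2L
  cs$trigger_count <- 2L                        # one dip tick short
  frame <- data.frame(time = 0, pressure_reading = 2, flow_reading = 0,
                      fio2_reading = 0.21)
  r <- control_tick(frame, s, g, cs, dt); cs <- r$state   # trigger fires
  expect_true(r$output$new_cycle_started)
  expect_true(r$output$spontaneous)
  cs <- controller_state()
  cs$phase <- "EXPIRE"
  cs$tick_in_cycle <- nt[["n_cycle"]]            # exactly at the boundary
  cs$trigger_count <- 2L
  r <- control_tick(frame, s, g, cs, dt)
  expect_true(r$output$new_cycle_started)
  expect_false(r$output$spontaneous)             # schedule won the tie
})

test_that("override forces safe outputs every tick until pressure recovers", {
  s <- midpoint_settings()
  g <- pid_gains()
  cs <- controller_state()
  frame <- function(p) data.frame(time = 0, pressure_reading = p,
                                  flow_reading = 0, fio2_reading = 0.21)
  for (i in 1:3) { r <- control_tick(frame(50), s, g, cs, 0.005); cs <- r$state }
  expect_true(cs$override_active)
  for (i in 1:10) {
    r <- control_tick(frame(48), s, g, cs, 0.005); cs <- r$state
    expect_equal(r$output$valve_drive, 0)
    expect_true(r$output$expiratory_valve_open)
    expect_true(r$output$safety_override)
  }
  r <- control_tick(frame(30), s, g, cs, 0.005); cs <- r$state
  expect_false(cs$override_active)
  expect_true("HAPA_CLEAR" %in% r$events)
})
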
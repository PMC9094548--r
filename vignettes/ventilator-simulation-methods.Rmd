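---
title: "Methods: closed-loop simulation of a pressure-controlled ventilator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop simulation of a pressure-controlled ventilator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcvsim)
```

# What the package models

`pcvsim` is a software testbench for a pressure-controlled, timed-cycle
mechanical ventilator of minimal open design: a proportional valve on the
inspiratory limb driven by a PID pressure controller, and a solenoid in
series with a spring-loaded mechanical PEEP valve on the expiratory limb. During inspiration the expiratory solenoid is closed and
the controller inflates the lung to the target peak inspiratory pressure
(PIP); the pressure ramp and the subsequent plateau are nothing more than
the PID transient while tracking a constant setpoint. At the set
inspiratory time the proportional valve closes and the solenoid opens, and
the lung empties passively against the PEEP valve until the next scheduled
cycle — or until a patient inspiratory effort is detected (SIMV-style
triggering), which re-synchronizes the cycle.

The plant is a **linear single-compartment lung**: compliance
$C$ (mL/cmH$_2$O), airway resistance $R$ (cmH$_2$O/(L/s)), so the elastic
recoil is $P_{alv} = V/C$ and the airway obeys $P_{aw} - P_{alv} = R\,Q$.
This is the standard equation-of-motion model realized physically by
adjustable test lungs, and it is what the package's condition grid sets:
$C \in \{5, 20, 50\}$ mL/cmH$_2$O $\times$
$R \in \{5, 20, 50\}$ cmH$_2$O/(L/s), plus a pediatric condition
($C = 10$, $R = 25$, with a 400 mL residual capacity). A residual capacity
is carried and reported but does not change the pressure–volume relation
(the model is linear); how a real pediatric test lung's uncompensated
residual volume bends its P–V curve is not modeled, which matters for the
inspired-volume comparison below.

## The pneumatic circuit

The circuit is solved quasi-statically at the patient wye: valve inflow
equals lung inflow plus expiratory outflow,

$$Q_{valve} = \frac{P_{aw} - P_{alv}}{R} + \frac{\max(P_{aw} -
P_{PEEP}, 0)}{R_{exp}} .$$

The expiratory path is an ideal threshold valve: no flow at or below the
PEEP setting, linear in the overpressure above it (spring dynamics are not
modeled). The proportional valve is an ideal flow source — supply pressure
(50 psi) is three orders of magnitude above airway pressures, so upstream
dynamics are ignored — scaled by the commanded drive in $[0,1]$ up to
`valve_max_flow` (default 85 L/min), with a **first-order actuator lag**
(`valve_tau`, default 30 ms). The lag deserves a note: an idealized
instantaneous valve lets a single 5 ms control tick impose its full flow
step on the airway, which at $R = 50$ produces a one-sample resistive
pressure spike no physical current-driven solenoid valve could produce.
With the lag the commanded flow develops over tens of milliseconds, as real
proportional valves do. Setting `valve_tau = 0` recovers the idealized
valve.

Tubing compliance, gas blending, humidification, FiO$_2$ dynamics (beyond a
static channel) and nonlinear or multi-compartment lungs are out of scope.
A nonzero `tubing_compliance` is lumped in parallel with the lung
compliance — a crude but conservative treatment, acceptable because the
default is zero.

## Units and integration

Internally: pressure cmH$_2$O, volume L, flow L/s, time s. Conversion to
the display units (mL, L/min) happens only at the I/O boundary. Physics
advances by explicit Euler at `dt_physics` (default 1 ms), validated
against the exponential closed form of the lung ODE to well under 1% of
$C\,\Delta P$; an exact-exponential stepper is available in `step_lung()`.
The controller runs every `dt_control` (default 5 ms, i.e. 200 Hz — chosen
so a 300 ms pressure ramp is resolved by 60 control decisions; the
waveform is sampled at this rate). Endurance runs use a coarse 10 ms step
for both clocks; at the midpoint condition (time constants
$\tau = RC = 0.4$ s inspiratory, $(R+R_{exp})C = 0.6$ s expiratory) the
integration error this introduces is negligible, but control fidelity on
much faster lungs ($\tau = 25$ ms) degrades at 10 ms, which is why the
coarse step is reserved for the endurance scenario.

# The controller

Each control tick, in strict priority order:

1. **Safety override.** If the sensed pressure exceeds the high-pressure
   alarm limit (default `min(PIP + 15, 60)` cmH$_2$O) for 3 consecutive
   ticks, the proportional valve is forced shut, the expiratory valve
   forced open, and the high-priority HAPA alarm raised. The override holds
   until the pressure falls below the limit; the controller then remains in
   expiration until the next scheduled cycle boundary. (Resuming
   inspiration immediately would re-pressurize into a still-active
   disturbance and make the alarm chatter.)
2. **Scheduled cycling.** Cycle positions are tracked as integer tick
   counts (no floating-point drift over multi-day runs). A scheduled cycle
   start beats a simultaneous detected breath; such a breath is not flagged
   spontaneous.
3. **Breath triggering.** During expiration, after a refractory window of
   20% of the expiratory time (guarding against valve-closure transients),
   a sensed pressure below `PEEP − trigger_sensitivity` for 3 consecutive
   ticks starts a new cycle flagged spontaneous.
4. **PID.** During inspiration the valve drive is
   $\mathrm{clamp}\!\left(f_a k_p e + k_i \int e\,dt + k_d \dot e_f,\ 0,\
   1\right)$ with $e$ the pressure error; $f_a$ is the clinician's *flow
   adjustment*, which scales the proportional gain only (larger values
   steepen the ramp). The integral is frozen while the output is saturated
   in the direction of the error and its contribution is clamped
   (`integral_clamp`, drive units); the derivative acts on a first-order
   filtered error (`deriv_tau`) and its state is re-initialized at each
   inspiration onset to avoid a derivative kick.

## Gain tuning

The controller gains are not physical constants; they are a design choice,
and the package treats the shipped defaults as a documented calibration.
The tuning protocol (reproducible from `pid_gains()` and the harness) was a
coarse-to-fine grid search over $(k_p, k_i, k_d,$ `integral_clamp`,
`deriv_tau`$)$ scoring every candidate on the full condition grid at zero
sensor noise, subject to the device's validated envelope:

* midpoint condition (C 20, R 20, PIP 30, PEEP 5): mean rise time
  $\le$ 300 ms and plateau within ±1 cmH$_2$O;
* worst-case mean-PIP deviation over the 3×3 grid $\le$ 9%;
* pediatric condition: mean $|$PIP $-$ 20$|$ $\le$ 1 cmH$_2$O;
* no high-pressure alarm on any nominal run.

The binding trade-off is instructive: a fast ramp on a compliant adult lung
wants high gain and integral action, but the same gains slam the stiff,
fast ($\tau = 25$ ms) C = 5 lungs, where valve momentum plus integral
unwind overshoot the peak pressure. The feasible region is reached with a
large proportional gain, a strong integral with tight anti-windup clamp,
and a small, heavily filtered derivative. The defaults are
$k_p = 0.13$, $k_i = 3$, $k_d = 0.004$ (drive per cmH$_2$O, cmH$_2$O·s,
cmH$_2$O/s), `integral_clamp` 0.5, `deriv_tau` 120 ms. With them the
midpoint rise time is ~245 ms, the grid-worst PIP deviation ~8% (at
C 5, R 5), and the pediatric PIP bias ~0.84 cmH$_2$O.

```{r, fig.width = 7, fig.height = 3.5}
cfg <- sim_config(vent_settings(30, 5, 15, "1:2"), lung_params(20, 20),
                  duration = 12, seed = 1)
res <- run_simulation(cfg)
plot(res$waveform$time_s, res$waveform$pressure_cmH2O, type = "l",
     xlab = "time (s)", ylab = expression(P[aw]~(cmH[2]*O)))
abline(h = c(30, 5), lty = 3)
```

# Sensors, noise and determinism

The sensor model is affine with additive Gaussian noise
(`reading = gain·truth + offset + N(0, sd)`); defaults 0.1 cmH$_2$O and
0.5 L/min. A miscalibrated pressure channel (gain/offset) propagates into
control errors of a few cmH$_2$O, which is why
`calibrate_pressure_sensor()` (two-point or least-squares affine fit
against known pressures) is part of the surface. One flow sensor exists; it
defaults to the expiratory side (expiratory flow and VTE are the displayed
quantities) but can be placed on the inspiratory side. The recorded
waveform's pressure channel is the *sensed* pressure the controller acted
on; flows and volume are physics truth. All stochastic draws come from R's
global generator seeded once per run, so identical configurations reproduce
bit-identically — the engine cross-check (compiled core vs. pure-R
reference loop) and the bundle re-simulation test rely on this.

# Events

Two disturbance kinds are scheduled through `event_spec()`:

* `SPONTANEOUS_EFFORT` subtracts its magnitude from the alveolar pressure —
  a one-parameter muscle-pressure pulse. It reproduces the observable a
  trigger must detect (a transient dip below PEEP) without modeling
  respiratory muscle mechanics. Whether a given effort dips below the
  trigger threshold depends on how much elastic recoil remains, so test
  scenarios place efforts late in expiration.
* `PRESSURE_TRANSIENT` adds its magnitude to the airway pressure — an
  external over-pressure used to exercise the HAPA response.

Magnitudes and durations are free parameters of a scenario; the defaults in
the examples (3–5 cmH$_2$O efforts, +20 cmH$_2$O transients) were chosen to
produce unambiguous detections at the default sensitivities.

# Metrics and alarms

Per breath: measured PIP (max inspiratory pressure), measured PEEP (mean
over the final 10% of expiration — configurable; the pressure sits at the
valve setting for the whole late expiratory phase), VTE (trapezoidal
integral of expiratory flow), inspired volume (integral of inspiratory
flow), rise time (first crossing of PIP $-$ 1 cmH$_2$O from inspiration
onset; the 1 cmH$_2$O band is a declared convention for "reached", and is
configurable), and mean airway pressure. Integrals run over the samples of
the corresponding phase only, so the flow discontinuity at the expiratory
valve opening does not smear into the trapezoid. `estimate_compliance()`
(VTE over the measured pressure span) is a consistency diagnostic: it
recovers the configured compliance within 5% at zero noise when both phases
last $\ge 5\tau$ and inflation is gentle enough not to overshoot (the
high-resistance overshoot otherwise inflates the denominator — use a
reduced flow adjustment for this diagnostic).

Alarm rules (Table: `alarm_rules()`) are split into tick-scope rules
(high pressure, low FiO$_2$, technical), whose detection latency is bounded
by persistence × control period, and breath-scope rules (low PIP,
hypo-/hyperventilation, obstruction, PEEP not met, disconnect/leak)
evaluated per completed breath. The specific thresholds are declared
defaults, not device-derived constants; every one is configurable. Episodes
open once per condition run and clear when it resolves; setting
`auto_acknowledge = FALSE` latches them (the safety-device convention —
the simulator default favors unattended batch runs). The pipeline extracts
episodes vectorized over the whole record; `evaluate_alarms()` is the
equivalent per-tick engine, and the two are tested against each other.

# What the simulations do and do not show

The harness reproduces, in silico, the test protocol a physical device
would face: the 3×3 compliance–resistance grid (pass: PIP within ±10%, VTE
inside the 100–500 mL window), the pediatric condition aggregated over
hundreds of cycles, and a 70,000-cycle endurance run streamed in chunks
with bounded memory (drift = first-vs-last 1000-cycle mean PIP). Because
the plant is the same linear model the controller was tuned against,
passing these bounds demonstrates the *control stack* (cycling, PID,
triggering, override, alarms, analytics) — it does not validate against
real lungs, real valve curves, sensor drift beyond the affine model, or
hardware timing jitter (the clock is idealized). One quantitative
consequence: the pediatric inspired volume simulates to ~136 mL, above the
~128 mL a hardware reference delivered, consistent with the unmodeled
residual-capacity nonlinearity of the physical pediatric test lung;
the closed-form bracket for the linear model is 100–150 mL with an
exponential bound near 136 mL.

Problem sizes used in the shipped checks: 30 s runs for ramp and alarm
latency, 25 cycles per grid condition, 300 cycles for the pediatric
aggregate, 70,000 cycles (10 ms steps, 500-cycle chunks) for endurance.

# Degenerate inputs and numerical conventions

Settings are validated at construction against the labeled clinical ranges
(PIP 15–60, PEEP 5–25, RR 10–40, I:E 1:1–1:3, PIP > PEEP);
`validate = FALSE` admits research-range values (e.g. very slow test lungs
needing 15 s inspirations) while keeping structural checks. Lung volume is
clamped at zero (a lung cannot be squeezed below residual). Non-finite
state aborts a run with an error rather than clipping. A trailing
incomplete breath is dropped by segmentation; a run shorter than one cycle
yields an empty breath table. Ties between a detected breath and the
scheduled cycle boundary go to the schedule.
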
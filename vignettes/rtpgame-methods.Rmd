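---
title: "Models and methods behind rtpgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rtpgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpgame)
```

`rtpgame` simulates a game-based rehabilitation platform for manual
dexterity — a one-axis manipulandum handle driving the paddle of a
catch-the-falling-target game — together with the kinematic and clinical
outcome pipeline used to quantify recovery. This vignette documents the
models, the parameters that matter, the numerical choices, and the
limits of what the simulation establishes.

## Device model

The handle is a rotary inertia with viscous damping:

$$I\,\ddot\theta = \tau_{player} + \tau_{field} - b\,\dot\theta,$$

with $I$ in kg·mm², torques in N·mm and $b$ in N·mm·s/rad (in this
millimetre system $\ddot\theta\,[\mathrm{rad/s^2}] = 1000\,\tau/I$). The
screen mapping is linear: the working range
$[\theta_{min}, \theta_{max}]$ maps onto 0–100% of screen width, with
clamping outside and hard stops (angle clamped, velocity zeroed) at the
limits, because the physical handle range is finite. A "sensitivity" of
$s$ degrees-per-full-screen is the same mapping expressed differently
and is converted internally to the range $[-s/2, s/2]$ about the neutral
angle. Orientation (horizontal/vertical play) only selects which screen
axis the position feeds; the mathematics are axis-agnostic.

The unidirectional force field adds a constant torque toward its
configured direction regardless of motion — assistive for movements that
way, resistive the other way — mirroring the hardware mode that helps
patients whose impairment is direction-asymmetric. The field is assumed
torque-controlled and constant; the source hardware description does not
state magnitudes, so `force_magnitude_Nmm`, `inertia_kgmm2` (default 50)
and `damping_Nmm_s_per_rad` (default 5) are exposed placeholders. No
kinematic result in the package depends on them (players command
positions by default); they matter only in the optional torque-tracking
mode.

**Integrator.** Because the per-step problem (constant torque over one
frame) is linear, `step_dynamics()` uses the exact exponential solution
of the damped system rather than a low-order numeric scheme. With the
default placeholder parameters the system time constant is
$I/(1000\,b) = 10$ ms, shorter than the 8.3 ms frame period; a
first-order integrator at that step would carry visible error, while the
closed form is exact for piecewise-constant torque and unconditionally
stable. A classical RK4 integrator at 100× finer steps serves as an
independent oracle in the test suite; agreement is required within
$10^{-3}$ degrees over 1-s horizons.

## Game engine

Events are back-to-back: $n = \lfloor T_{session}/T_{event}\rfloor$
events, each a target appearing at the top of the screen and descending
linearly to the paddle line over `event_duration_s` (default 2 s, so a
60-s session has 30 events). A target is caught iff at its landing frame
the centre separation does not exceed the sum of half-widths (closed
inequality — touching counts; the simplest deterministic tie-break).
Objects always complete their fall; a miss does not end an event early.
Distractor objects share the event window, carry no required direction,
and can contact the paddle — that contact is annotated but never scored,
since the source platform defines no penalty.

"Approximately half" of events in each direction is implemented as an
exactly balanced pre-shuffled direction sequence (within one for odd
counts): exact balance is what makes unweighted per-direction averaging
well defined. Each spawn is drawn uniformly on the required side of the
expected paddle position (the previous target's landing spot), at least
`min_amplitude_pct` (default 10%) away so every event demands a real
movement, inside the strip that keeps the target fully on screen.
"Unpredictable speeds" are available as optional per-event duration
jitter (`duration_jitter_fraction`, default 0).

All randomness in a session — schedule, player draws, tremor — flows
from the single `seed` in the game config; two runs with equal configs
are identical objects.

## Virtual players (synthetic data)

No generative model of patient movement is given by the platform
description; the player model is an artifact construct designed to
reproduce the qualitative phenotypes visible in game trajectory
overlays: able-bodied responses are prompt, smooth, accurate and
consistent; stroke-like responses show delayed onset, reduced amplitude,
non-smooth paths and target overshoots.

A response to an event is:

1. a reaction latency drawn from a normal truncated at zero
   (`onset_latency_mean`, `onset_latency_sd`);
2. a minimum-jerk primary movement covering `amplitude_gain` of the
   required amplitude, lasting `movement_time_per_amplitude` seconds per
   percent travelled (floor 0.1 s);
3. with probability `submovement_prob` (repeatedly, up to 3), a
   corrective minimum-jerk sub-movement aimed at
   $(1 + \text{overshoot\_gain})$ times the residual error — positive
   overshoot gains produce the past-the-target excursions typical of
   impaired control;
4. tremor: white noise low-pass filtered at 8 Hz (the physiological
   tremor band), with stationary SD `tremor_sd` percent, superimposed
   continuously across the session.

The four presets were calibrated **once** on 50-seed default-game
averages and then frozen: able-bodied catches 100% of targets; the
stroke presets land at 78.0% (mild), 61.3% (moderate) and 51.7%
(severe), inside the 50–80% success-rate band reported for a patient
across manipulation tasks, and degrade monotonically in success rate and
(normalized) variability.

What a green phenotype test establishes: the pipeline distinguishes
graded, plausibly shaped impairment under this generative model. What it
does not: that real patients move like this. The model has no learning,
no fatigue, no biomechanics, no direction-specific weakness, and its
parameters are not fitted to patient data.

## Metric pipeline

**Segmentation.** One trace per target event, windowed from appearance
to disappearance, displacement re-referenced to the paddle position at
appearance and signed so movement in the required leftward direction is
positive (the direction-sorted overlay convention).

**Movement onset (MOT / response time).** The platform defines MOT
verbally ("time from target appearance to the start of paddle
movement"); the operational rule here is: the earliest sample at which
|displacement| reaches 2% of screen with no sample in the following
50 ms falling back below (a window clipped by the trace end counts).
Displacement (not velocity) thresholding is robust to tremor;
both parameters are exposed. MOT in milliseconds is reported as
`response_time_ms` — the two are the same quantity in different units.
An exhaustive-scan oracle over all sample times must agree exactly on
1,000 random traces.

Threshold crossing necessarily lags true movement start (a minimum-jerk
reach needs time to cover 2% of screen), so raw MOT overestimates the
player's latency by roughly 0.1–0.2 s depending on movement speed.
`recover_player_parameters()` therefore back-extrapolates each crossing
using the cubic early-growth law of the minimum-jerk profile
($d \propto (t-t_0)^3$ gives $t_0 = t_c - 3d/v$) and takes per-session
medians; over 10 random player models at 200 events each, latency is
recovered within 0.05 s and amplitude gain within 0.1. The estimator is
model-aware by design — it validates the generator/pipeline pair, not an
assumption-free patient measurement.

**Success rate.** Percent of targets caught, per direction, averaged
unweighted across directions (the reporting convention of the per-object
assessment tables), even when counts differ by one.

**Kinematics.** Movement duration (onset to the last time speed exceeds
5%/s), peak |displacement|, final error at disappearance, and overshoot
count — the number of displacement excursions beyond the required
amplitude, with a 0.5% dead-band so tremor-level grazing does not count.

**Variability.** The direct definition — mean over 100 normalized time
points of the across-trace SD of displacement — is available
(`normalize = "none"`) but is dominated by task diversity: spawns are
randomized, so an accurate player tracking targets 10–50% away shows
*larger* raw across-trace spread than a hypometric impaired player. We
measured exactly this inversion (able 16.9% vs severe 4.9% of screen).
Since the quantity of interest is the player's trial-to-trial
consistency, `session_summary()` uses `normalize = "movement"`: each
trace restricted to its movement epoch (onset to stop), displacement
rescaled by required amplitude (denominator clipped at 10% of screen so
near-zero amplitudes after a missed previous target cannot dominate) and
time rescaled by epoch duration. Every ideal response then collapses
onto the same unit curve, and the measure grows with latency jitter,
corrections and tremor — restoring the intended able < mild < moderate <
severe ordering.

## Clinical outcomes

WMFT records hold 15 task times (each capped at 120 s) and 15 ordinal
functional ability scores (FAS, 0–5; summed maximum 75). Change scores
are reported as improvements: FAS post − pre, time pre − post. MCID
flags use strict inequality ("surpassed"); the FAS default threshold is
the conservative upper bound (6 points) of the published 3–6 range, and
the time threshold is 22 s, both configurable.

Group cells are "mean (sample SD)" with $n-1$ denominators — verified
against the printed tables (e.g. changes 9, 15, 14, 16, 14 give SD 2.70
→ "3", whereas the population SD 2.42 would print "2") — rounded
half-away-from-zero to integers. On this particular data no cell sits on
a .5 tie, so banker's rounding happens to agree everywhere; the
convention is exercised on synthetic ties in the unit tests.
`reproduce_tables()` rebuilds all 40 summary cells (WMFT table,
per-object assessment table, and the four group headline numbers) from
the raw per-participant fixture CSVs and diffs them against the
transcribed printed values.

Fixture notes: one source value is printed with a trailing period
("786.") and is transcribed as 786; the published narrative range for
time-MCID exceeders (23–28 s) is inconsistent with the printed table
changes (24–48 s) — the fixtures follow the table.

## Numerical and interface choices

- Frame rate defaults to 120 Hz everywhere (game logging and device
  stepping share the clock).
- The run config is one JSON file with `device`, `game`, `player`,
  `metrics` sections; unknown sections or keys are rejected by name, and
  a top-level `seed` overrides the game seed. JSON was chosen over TOML
  because the target environment ships a JSON parser only.
- Session logs serialize as a long frames CSV plus a JSON sidecar
  (schema-versioned); the write→read round trip is lossless to text
  precision.
- Report rounding is half-away-from-zero (`round_half_up()`), applied
  only at rendering; all aggregation is done unrounded.

## Known limitations

- The player model is phenomenological; preset parameters are frozen
  calibration artifacts, not patient estimates.
- Torque mode uses a simple PD tracker with fixed internal gains; it is
  a demonstration of force-field coupling, not a motor-control model.
- The catch rule evaluates overlap only at the landing frame, not
  during the fall.
- Encoder quantization, USB latency and rendering are out of scope; the
  paddle equals the mapped handle angle exactly.
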
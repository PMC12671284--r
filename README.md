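# rtpgame

Simulation and assessment pipeline for game-based rehabilitation of hand
function after stroke.

## The problem

Many people live with reduced manual dexterity after a stroke. One
practical therapy platform is a small one-axis robotic manipulandum: a
motorized handle whose shaft rotation acts as a high-resolution computer
mouse, so that thumb, finger or wrist movements steer the paddle of a
simple "catch the falling target" computer game. The same game doubles
as a measurement instrument — it logs every paddle and object position,
so each 60-second trial yields objective kinematic outcomes (success
rate, movement onset/response time, movement duration, amplitude,
overshoots, trial-to-trial variability) alongside conventional clinical
scores such as the Wolf Motor Function Test (WMFT).

`rtpgame` is a software twin of that platform for method development and
validation without hardware or patients. It provides:

- **`device_config()` / `step_dynamics()`** — the handle model: a linear
  map of the working range `[θ_min, θ_max]` (degrees) onto `[0, 100]` %
  of screen, and rotary dynamics `I·θ̈ = τ_player + τ_field − b·θ̇` with a
  unidirectional constant force field (assistive one way, resistive the
  other) and hard stops at the range limits.
- **`game_config()` / `schedule_events()` / `run_session()`** — the game:
  back-to-back 2-s events (30 per 60-s session), randomized spawn
  positions with an enforced left/right balance, optional distractors,
  closed-interval overlap catch rule, frame-level logging at 120 Hz.
- **`player_model()` / `player_preset()`** — virtual players. A response
  is a sampled reaction latency, a minimum-jerk primary movement
  `x(s) = x₀ + A·(10s³ − 15s⁴ + 6s⁵)` covering `gain × A` of the required
  amplitude, optional corrective sub-movements with overshoot, and
  8-Hz-low-pass tremor. Presets span able-bodied through severe
  stroke-like phenotypes.
- **`session_summary()` and friends** — the metric pipeline: trace
  segmentation, threshold-plus-hold movement-onset detection (MOT; in ms
  it is the "response time"), per-direction success rates averaged
  unweighted, kinematics and variability.
- **`wmft_outcome_table()` / `assessment_table()` /
  `reproduce_tables()`** — clinical scoring: WMFT totals (15 tasks, FAS
  0–5 each, max 75; 120-s task time cap), pre/post change scores, MCID
  flagging (defaults: 6 FAS points, 22 s), and the group "Average (SD)"
  tables (sample SD, half-away-from-zero rounding) rebuilt from the
  bundled per-participant fixture CSVs in `inst/extdata/`.

## Worked example

```r
library(rtpgame)
log <- run_session(game = game_config(seed = 1),
                   player = player_preset("stroke_moderate"))
log
#> <rtp_session_log>
#>   7201 frames at 120 Hz, 30 target events, 0 distractors
#>   caught 19/30 (63.3%)
session_summary(log)
#> <rtp_session_metrics>
#>   SR: left 66.7 right 60.0 avg 63.3 %
#>   MOT: left 0.715 right 0.578 avg 0.647 s (646.5 ms)
#>   duration 1.34 s, peak amplitude 22.6 %, overshoots 2.86, final error 8.3 %
#>   variability 26.6 % (n left 15, right 15)
```

Read: this moderately impaired virtual player caught 19 of 30 targets
(success rate 63.3%, the unweighted mean of 66.7% leftward and 60.0%
rightward), started moving on average 647 ms after target appearance
(close to the ~600 ms typical of patients on this task), moved with
reduced amplitude (22.6% of screen against required amplitudes of
10–50%), overshot the target about 3 times per response and ended 8.3%
of screen away from it on average. An able-bodied preset on the same
game catches 30/30 with ~270 ms response times.

The clinical side, from the bundled fixtures:

```r
reproduce_tables()$wmft$summary$fas_change$cell   # "14 (3)"
reproduce_tables()$assessment$group$sr_change$cell # "23 (12)"
```

## Command line

```sh
Rscript inst/cli/rtp-game simulate --preset stroke_moderate --seed 1 --out session
Rscript inst/cli/rtp-game analyze --log session --out metrics
Rscript inst/cli/rtp-game reproduce-tables
Rscript inst/cli/rtp-game presets
```

`simulate` writes `session_frames.csv` (long frame table) and
`session_meta.json` (schedule, catches, config snapshot, seed);
`reproduce-tables` rebuilds every group summary cell from the raw
fixtures, diffs them against the transcribed printed values and exits
nonzero on any mismatch.

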
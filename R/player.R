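#' Parameterise a virtual player
#'
#' Virtual players are the package's synthetic-data generator: they stand
#' in for patients so the whole game + metrics pipeline can be exercised
#' and validated by parameter recovery. The generative model is a
#' deliberately simple description of goal-directed reaching: after a
#' sampled reaction latency the player executes a smooth minimum-jerk
#' primary movement toward a (possibly hypometric) fraction of the
#' required amplitude, optionally followed by corrective sub-movements
#' that may overshoot, with low-pass-filtered tremor noise superimposed.
#' None of these parameters are measured patient quantities; they are
#' modelling constructs chosen to reproduce the qualitative phenotypes
#' seen in game trajectories: able-bodied responses are prompt, smooth and
#' accurate, stroke-like responses show delayed onset, reduced amplitude,
#' non-smooth paths and target overshoots.
#'
#' @param onset_latency_mean mean reaction latency, s (>= 0).
#' @param onset_latency_sd latency standard deviation, s; sampled from a
#'   normal truncated at zero.
#' @param amplitude_gain fraction of the required amplitude covered by the
#'   primary movement, in (0, 1.5]; 1 = accurate, < 1 = hypometric.
#' @param movement_time_per_amplitude movement time per percent of screen
#'   travelled, s/percent (primary movement duration scales with distance).
#' @param tremor_sd stationary standard deviation of tremor noise, percent
#'   of screen; white noise low-pass filtered at 8 Hz (physiological
#'   tremor band).
#' @param submovement_prob probability that a corrective sub-movement is
#'   issued after the previous movement ends, in [0, 1].
#' @param overshoot_gain corrective sub-movements aim for
#'   `(1 + overshoot_gain)` times the residual error (>= 0); positive
#'   values produce target overshoots.
#' @param mode `"kinematic"` (player commands paddle positions directly;
#'   default, keeps metric validation independent of handle dynamics) or
#'   `"torque"` (commands are fed through the device dynamics as a
#'   proportional-derivative tracking torque).
#' @return an object of class `rtp_player`.
#' @seealso [player_preset()] for documented severity bundles.
#' @export
player_model <- function(onset_latency_mean = 0.2,
                         onset_latency_sd = 0.05,
                         amplitude_gain = 1,
                         movement_time_per_amplitude = 0.015,
                         tremor_sd = 0,
                         submovement_prob = 0,
                         overshoot_gain = 0,
                         mode = "kinematic") {
  check_number(onset_latency_mean, "onset_latency_mean", lo = 0)
  check_number(onset_latency_sd, "onset_latency_sd", lo = 0)
  check_number(amplitude_gain, "amplitude_gain",
               lo = .Machine$double.eps, hi = 1.5)
  check_number(movement_time_per_amplitude, "movement_time_per_amplitude",
               lo = .Machine$double.eps)
  check_number(tremor_sd, "tremor_sd", lo = 0)
  check_number(submovement_prob, "submovement_prob", lo = 0, hi = 1)
  check_number(overshoot_gain, "overshoot_gain", lo = 0)
  check_choice(mode, "mode", c("kinematic", "torque"))
  structure(
    list(onset_latency_mean = onset_latency_mean,
         onset_latency_sd = onset_latency_sd,
         amplitude_gain = amplitude_gain,
         movement_time_per_amplitude = movement_time_per_amplitude,
         tremor_sd = tremor_sd,
         submovement_prob = submovement_prob,
         overshoot_gain = overshoot_gain,
         mode = mode),
    class = "rtp_player")
}

#' @export
print.rtp_player <- function(x, ...) {
  cat("<rtp_player>\n")
  for (f in setdiff(names(x), "mode")) cat(sprintf("  %s: %g\n", f, x[[f]]))
  cat(sprintf("  mode: %s\n", x$mode))
  invisible(x)
}

#' Minimum-jerk position profile
#'
#' The standard smooth-reach primitive: the unique quintic from `x0` (at
#' rest) to `x1` (at rest) minimising integrated squared jerk,
#' `x(t) = x0 + (x1 - x0) (10 s^3 - 15 s^4 + 6 s^5)` with `s = t/T`.
#'
#' @param x0,x1 start and end positions (percent of screen).
#' @param T_total movement duration, s (> 0).
#' @param t time(s) since movement start, in `[0, T_total]`.
#' @return position(s) at `t`.
#' @export
#' @examples
#' minimum_jerk(0, 10, 1, c(0, 0.5, 1)) # 0 5 10
minimum_jerk <- function(x0, x1, T_total, t) {
  check_number(T_total, "T_total", lo = .Machine$double.xmin)
  if (any(t < -1e-12 | t > T_total + 1e-12)) {
    stop_rtp("t must lie in [0, T_total]")
  }
  s <- clamp(t / T_total, 0, 1)
  x0 + (x1 - x0) * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

# One movement plan: latency + minimum-jerk primary + corrective
# sub-movements, returned as a piecewise segment table. Consumes RNG.
plan_response <- function(player, amplitude, event_duration,
                          max_submovements = 3L) {
  latency <- rtruncnorm0(1L, player$onset_latency_mean,
                         player$onset_latency_sd)
  segs <- list()
  pos <- 0
  t0 <- latency
  target <- amplitude
  d <- player$amplitude_gain * amplitude
  for (k in seq_len(max_submovements + 1L)) {
    T_mov <- max(player$movement_time_per_amplitude * abs(d), 0.1)
    segs[[k]] <- c(t_start = t0, from = pos, to = pos + d, T_mov = T_mov)
    pos <- pos + d
    t0 <- t0 + T_mov
    resid <- target - pos
    if (t0 >= event_duration || abs(resid) < 0.5) break
    if (stats::runif(1L) >= player$submovement_prob) break
    d <- (1 + player$overshoot_gain) * resid
  }
  do.call(rbind, segs)
}

# Evaluate a plan at event-relative times (no tremor).
eval_plan <- function(plan, t, start_x) {
  x <- rep(start_x, length(t))
  for (k in seq_len(nrow(plan))) {
    seg <- plan[k, ]
    rel <- t - seg[["t_start"]]
    active <- rel > 0
    x[active] <- start_x + minimum_jerk(seg[["from"]], seg[["to"]],
                                        seg[["T_mov"]],
                                        pmin(rel[active], seg[["T_mov"]]))
  }
  x
}

#' Generate a player's intended response to one game event
#'
#' Samples a reaction latency, plans a primary minimum-jerk movement from
#' the current paddle position toward `amplitude_gain` times the required
#' amplitude, optionally appends corrective sub-movements (each aimed at
#' `(1 + overshoot_gain)` times the residual error), and evaluates the
#' intended paddle position at the requested times. Tremor noise is *not*
#' added here; [run_session()] superimposes it over the whole session so
#' that it is continuous across events.
#'
#' This function draws from the R random number stream; seed control is
#' the caller's responsibility ([run_session()] seeds from the game
#' config).
#'
#' @param player an [player_model()] object.
#' @param event one row of a [schedule_events()] table (a list or
#'   data.frame row with `t_appear_s`, `t_disappear_s`, `x_spawn_pct`).
#' @param current_x paddle position (percent) when the event appears.
#' @param t times at which to evaluate the intended position; absolute
#'   session seconds within the event window.
#' @return data.frame with columns `t` and `x` (intended paddle percent).
#' @export
respond <- function(player, event, current_x, t) {
  stopifnot(inherits(player, "rtp_player"))
  event <- as.list(event)
  dur <- event$t_disappear_s - event$t_appear_s
  amplitude <- event$x_spawn_pct - current_x
  plan <- plan_response(player, amplitude, dur)
  data.frame(t = t, x = eval_plan(plan, t - event$t_appear_s, current_x))
}

#' Severity presets for the virtual player
#'
#' Documented parameter bundles spanning the phenotypes visible in game
#' trajectory overlays: an able-bodied player (prompt, smooth, accurate;
#' catches every target of the default game) and three graded stroke-like
#' players (increasingly delayed onset, reduced amplitude, more corrective
#' sub-movements and overshoot, more tremor). The stroke bundles were
#' tuned once so that their default-game success rates fall in the 50-80%
#' band observed for a patient across manipulation tasks, then frozen.
#'
#' @param profile one of `"able_bodied"`, `"stroke_mild"`,
#'   `"stroke_moderate"`, `"stroke_severe"`.
#' @return an [player_model()] object.
#' @export
player_preset <- function(profile = c("able_bodied", "stroke_mild",
                                      "stroke_moderate", "stroke_severe")) {
  profile <- match.arg(profile)
  switch(profile,
    able_bodied = player_model(
      onset_latency_mean = 0.18, onset_latency_sd = 0.03,
      amplitude_gain = 1, movement_time_per_amplitude = 0.012,
      tremor_sd = 0.2, submovement_prob = 0.1, overshoot_gain = 0.05),
    stroke_mild = player_model(
      onset_latency_mean = 0.45, onset_latency_sd = 0.10,
      amplitude_gain = 0.80, movement_time_per_amplitude = 0.034,
      tremor_sd = 1.0, submovement_prob = 0.50, overshoot_gain = 0.25),
    stroke_moderate = player_model(
      onset_latency_mean = 0.60, onset_latency_sd = 0.15,
      amplitude_gain = 0.70, movement_time_per_amplitude = 0.042,
      tremor_sd = 1.2, submovement_prob = 0.55, overshoot_gain = 0.35),
    stroke_severe = player_model(
      onset_latency_mean = 0.80, onset_latency_sd = 0.20,
      amplitude_gain = 0.66, movement_time_per_amplitude = 0.048,
      tremor_sd = 1.6, submovement_prob = 0.65, overshoot_gain = 0.45))
}

#' Recover player parameters from segmented traces
#'
#' Validation estimator for the synthetic-data generator: given the
#' per-event traces of a session, estimates the player's mean onset
#' latency and amplitude gain.
#'
#' The raw threshold-crossing movement onset time carries a systematic
#' approach lag (a minimum-jerk movement needs time to cover the
#' displacement threshold). For a minimum-jerk profile the early
#' displacement grows as `d ~ (t - t0)^3`, so `t0 = t_c - 3 d(t_c) /
#' v(t_c)` exactly in the early phase; the estimator back-extrapolates
#' each detected crossing with this cubic rule. The amplitude gain is
#' estimated as the displacement at the end of the primary movement
#' (first time after peak speed that speed drops below 5% of its peak)
#' divided by the required amplitude.
#'
#' @param traces a list of traces from [segment_responses()].
#' @param displacement_threshold onset threshold, percent (default 2).
#' @param min_hold hold time for the onset rule, s (default 0.05).
#' @return list with `onset_latency_mean` and `amplitude_gain` (medians
#'   of the per-trace estimates, robust to the minority of traces where a
#'   correction merges with the primary movement), plus the per-trace
#'   vectors `latency` and `gain` (NA where no onset was detected).
#' @export
recover_player_parameters <- function(traces, displacement_threshold = 2,
                                      min_hold = 0.05) {
  lat <- rep(NA_real_, length(traces))
  gain <- rep(NA_real_, length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    mot <- detect_onset(tr, displacement_threshold, min_hold)
    if (is.na(mot)) next
    t <- tr$samples$t
    d <- tr$samples$displacement
    n <- length(t)
    # tremor makes frame-to-frame differences useless; smooth with a
    # short moving average (~60 ms) before differentiating
    w <- min(7L, n - (1 - n %% 2))
    dsm <- if (w >= 3L) {
      as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
    } else d
    dsm[is.na(dsm)] <- d[is.na(dsm)]
    ic <- which(t >= mot - 1e-12)[1L]
    # early minimum-jerk displacement grows cubically, so the true start
    # is t_c - 3 d(t_c)/v(t_c); slope over +/- 2 frames at the crossing
    i0 <- max(1L, ic - 2L)
    i1 <- min(n, ic + 2L)
    v <- (dsm[i1] - dsm[i0]) / (t[i1] - t[i0])
    if (is.finite(v) && v > 1e-9) {
      lat[i] <- max(mot - 3 * max(dsm[ic], 0) / v, 0)
    } else {
      lat[i] <- mot
    }
    # primary-movement endpoint: first local minimum of the smoothed
    # speed after its peak, provided the dip is well below the peak --
    # consecutive minimum-jerk segments meet at (near) zero velocity, so
    # this also separates a primary movement from an immediate correction
    if (tr$required_amplitude > 1e-9 && ic < n - 2L) {
      vel <- diff(dsm) / diff(t)
      sp <- abs(vel)
      vpk_i <- ic - 1L + which.max(sp[ic:length(sp)])
      vpk <- sp[vpk_i]
      m <- length(sp)
      stop_i <- NA_integer_
      if (vpk_i + 1L < m) {
        for (k in (vpk_i + 1L):(m - 1L)) {
          if (sp[k] <= sp[k - 1L] && sp[k] <= sp[k + 1L] &&
              sp[k] < 0.15 * vpk) {
            stop_i <- k
            break
          }
        }
      }
      if (is.na(stop_i)) {
        stop_i <- which(sp < 0.05 * vpk & seq_along(sp) > vpk_i)[1L]
      }
      if (!is.na(stop_i)) {
        gain[i] <- dsm[stop_i + 1L] / tr$required_amplitude
      }
    }
  }
  # medians: endpoint detection occasionally merges a primary movement
  # with an immediate correction, contaminating a minority of traces
  # with post-correction positions; the median ignores that mode
  list(onset_latency_mean = stats::median(lat, na.rm = TRUE),
       amplitude_gain = stats::median(gain, na.rm = TRUE),
       latency = lat, gain = gain)
}
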
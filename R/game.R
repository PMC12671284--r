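#' Configure the catch-the-target game
#'
#' The repetitive-task-practice game shows falling objects that the player
#' catches by steering a paddle along one screen axis with the device
#' handle. Events are back-to-back: each target appears at the top of the
#' screen at a randomized horizontal position and descends to the paddle
#' line over `event_duration_s` seconds (2 s by default, giving 30 events
#' in a standard 60 s session). Approximately half of the events require a
#' leftward movement and half a rightward movement; the scheduler enforces
#' an exactly balanced split (within 1 for odd counts) so per-direction
#' metrics are well defined.
#'
#' @param session_duration_s total session length, s (default 60).
#' @param event_duration_s one target's fall time, appearance to
#'   disappearance, s (default 2).
#' @param paddle_width_pct,target_width_pct sprite widths, percent of
#'   screen, in (0, 100).
#' @param distractors_enabled if `TRUE`, each event also spawns
#'   `distractors_per_event` non-target objects that must be ignored.
#' @param distractors_per_event distractor count per event.
#' @param frame_rate_hz logging/physics frame rate (default 120).
#' @param duration_jitter_fraction optional per-event uniform jitter of
#'   the event duration (fraction of `event_duration_s`, default 0),
#'   realising "unpredictable speeds".
#' @param min_amplitude_pct minimum distance between the expected paddle
#'   position and a new spawn, percent (default 10), so every event
#'   demands an actual movement.
#' @param seed integer seed; all session randomness (schedule, player,
#'   tremor) flows from it.
#' @return an object of class `rtp_game_config`.
#' @export
game_config <- function(session_duration_s = 60,
                        event_duration_s = 2,
                        paddle_width_pct = 10,
                        target_width_pct = 5,
                        distractors_enabled = FALSE,
                        distractors_per_event = 1L,
                        frame_rate_hz = 120,
                        duration_jitter_fraction = 0,
                        min_amplitude_pct = 10,
                        seed = 1L) {
  check_number(session_duration_s, "session_duration_s",
               lo = .Machine$double.eps)
  check_number(event_duration_s, "event_duration_s",
               lo = .Machine$double.eps)
  check_number(paddle_width_pct, "paddle_width_pct",
               lo = 1e-9, hi = 100 - 1e-9)
  check_number(target_width_pct, "target_width_pct",
               lo = 1e-9, hi = 100 - 1e-9)
  stopifnot(isTRUE(distractors_enabled) || isFALSE(distractors_enabled))
  check_number(distractors_per_event, "distractors_per_event", lo = 0)
  check_number(frame_rate_hz, "frame_rate_hz", lo = .Machine$double.eps)
  check_number(duration_jitter_fraction, "duration_jitter_fraction",
               lo = 0, hi = 0.5)
  check_number(min_amplitude_pct, "min_amplitude_pct", lo = 0, hi = 50)
  check_number(seed, "seed")
  structure(
    list(session_duration_s = session_duration_s,
         event_duration_s = event_duration_s,
         paddle_width_pct = paddle_width_pct,
         target_width_pct = target_width_pct,
         distractors_enabled = distractors_enabled,
         distractors_per_event = as.integer(distractors_per_event),
         frame_rate_hz = frame_rate_hz,
         duration_jitter_fraction = duration_jitter_fraction,
         min_amplitude_pct = min_amplitude_pct,
         seed = as.integer(seed)),
    class = "rtp_game_config")
}

#' Schedule the game events of one session
#'
#' Lays out `floor(session_duration / event_duration)` back-to-back
#' events. The required movement direction sequence is an exactly balanced
#' left/right split (within 1 for odd counts), pre-shuffled; each spawn x
#' is drawn uniformly on the required side of the expected paddle position
#' (the previous target's landing spot), at least `min_amplitude_pct`
#' away, inside the feasible strip
#' `[target_width/2, 100 - target_width/2]`. With distractors enabled,
#' each event additionally spawns distractor objects anywhere in the
#' strip; distractors carry no required direction and never score.
#'
#' Draws from the R random stream; [run_session()] seeds it from
#' `config$seed`.
#'
#' @param config an [game_config()] object.
#' @param initial_paddle_x paddle position at session start, percent
#'   (default 50, screen centre).
#' @return data.frame of events: `event_id`, `kind` ("target" or
#'   "distractor"), `t_appear_s`, `t_disappear_s`, `x_spawn_pct`,
#'   `required_direction` ("leftward"/"rightward", NA for distractors).
#'   Zero rows (with a warning) if the session is shorter than one event.
#' @export
schedule_events <- function(config, initial_paddle_x = 50) {
  stopifnot(inherits(config, "rtp_game_config"))
  check_number(initial_paddle_x, "initial_paddle_x", lo = 0, hi = 100)
  D <- config$event_duration_s
  n <- floor(config$session_duration_s / D + 1e-9)
  if (n < 1L) {
    warning("session shorter than one event: empty schedule")
    return(data.frame(event_id = integer(), kind = character(),
                      t_appear_s = numeric(), t_disappear_s = numeric(),
                      x_spawn_pct = numeric(),
                      required_direction = character()))
  }
  half <- n %/% 2L
  dirs <- sample(c(rep("leftward", half), rep("rightward", n - half)))
  jit <- if (config$duration_jitter_fraction > 0) {
    stats::runif(n, -config$duration_jitter_fraction,
                 config$duration_jitter_fraction)
  } else rep(0, n)
  durs <- D * (1 + jit)
  t_app <- cumsum(c(0, durs[-n]))
  lo <- config$target_width_pct / 2
  hi <- 100 - config$target_width_pct / 2
  ref <- initial_paddle_x
  xs <- numeric(n)
  for (i in seq_len(n)) {
    if (dirs[i] == "leftward") {
      upper <- ref - config$min_amplitude_pct
      if (upper <= lo) upper <- ref - 1
      xs[i] <- if (upper <= lo) lo else stats::runif(1L, lo, upper)
    } else {
      lower <- ref + config$min_amplitude_pct
      if (lower >= hi) lower <- ref + 1
      xs[i] <- if (lower >= hi) hi else stats::runif(1L, lower, hi)
    }
    ref <- xs[i]
  }
  ev <- data.frame(event_id = seq_len(n), kind = "target",
                   t_appear_s = t_app, t_disappear_s = t_app + durs,
                   x_spawn_pct = xs, required_direction = dirs,
                   stringsAsFactors = FALSE)
  if (config$distractors_enabled && config$distractors_per_event > 0L) {
    nd <- n * config$distractors_per_event
    dx <- stats::runif(nd, lo, hi)
    di <- rep(seq_len(n), each = config$distractors_per_event)
    dev <- data.frame(event_id = n + seq_len(nd), kind = "distractor",
                      t_appear_s = t_app[di],
                      t_disappear_s = t_app[di] + durs[di],
                      x_spawn_pct = dx,
                      required_direction = NA_character_,
                      stringsAsFactors = FALSE)
    ev <- rbind(ev, dev)
  }
  ev
}

#' Catch test: paddle/target overlap at the paddle line
#'
#' A target is caught when, at the frame it reaches the paddle line, the
#' horizontal separation of the two sprite centres does not exceed the sum
#' of their half-widths. Touching counts (closed inequality) -- the
#' deterministic, simplest tie-break.
#'
#' @param paddle_x,target_x sprite centres, percent of screen.
#' @param paddle_width,target_width sprite widths, percent (> 0).
#' @return logical, `TRUE` if caught. Vectorised.
#' @export
catch_test <- function(paddle_x, paddle_width, target_x, target_width) {
  stopifnot(all(paddle_width > 0), all(target_width > 0))
  abs(target_x - paddle_x) <= (paddle_width + target_width) / 2
}

# Vertical position of an object at time t: descends linearly from 100 to
# 0 over its event window.
object_y <- function(t, t_appear, t_disappear) {
  clamp(100 * (1 - (t - t_appear) / (t_disappear - t_appear)), 0, 100)
}

#' Create an empty session log
#'
#' Container holding the frame record, the event schedule, per-target
#' catch flags and per-distractor contact annotations, plus the config
#' snapshots needed to interpret them. Used directly with [game_step()]
#' for incremental stepping; [run_session()] fills one in a single pass.
#'
#' @param game an [game_config()] object.
#' @param events event table from [schedule_events()].
#' @param device,player optional config snapshots stored for provenance.
#' @param seed the seed the schedule/player randomness flowed from.
#' @return an object of class `rtp_session_log`.
#' @export
empty_session_log <- function(game, events, device = NULL, player = NULL,
                              seed = NA_integer_) {
  stopifnot(inherits(game, "rtp_game_config"), is.data.frame(events))
  tgt <- events[events$kind == "target", , drop = FALSE]
  dis <- events[events$kind == "distractor", , drop = FALSE]
  structure(
    list(schema_version = 1L,
         frames = data.frame(t_s = numeric(), paddle_x_pct = numeric()),
         events = events,
         catches = data.frame(event_id = tgt$event_id,
                              caught = rep(NA, nrow(tgt))),
         annotations = data.frame(event_id = dis$event_id,
                                  distractor_contact = rep(NA, nrow(dis))),
         game = game, device = device, player = player,
         seed = as.integer(seed)),
    class = "rtp_session_log")
}

#' Advance the game one frame
#'
#' Appends one frame at the paddle position supplied and resolves the
#' catch flag of any target whose fall completes at the new frame time
#' (objects always complete their fall; a miss does not end the event
#' early). Distractor contact at the landing frame is annotated but never
#' scored.
#'
#' @param log an `rtp_session_log` (see [empty_session_log()]).
#' @param paddle_x paddle centre at the new frame, percent.
#' @param dt frame period, s; must equal `1/frame_rate_hz`.
#' @return the updated log.
#' @export
game_step <- function(log, paddle_x, dt) {
  stopifnot(inherits(log, "rtp_session_log"))
  if (abs(dt - 1 / log$game$frame_rate_hz) > 1e-9) {
    stop_rtp("dt must equal 1/frame_rate_hz")
  }
  nf <- nrow(log$frames)
  t_new <- if (nf == 0L) 0 else log$frames$t_s[nf] + dt
  log$frames <- rbind(log$frames,
                      data.frame(t_s = t_new, paddle_x_pct = paddle_x))
  t_prev <- if (nf == 0L) -Inf else log$frames$t_s[nf]
  ev <- log$events
  landing <- ev$t_disappear_s > t_prev + 1e-9 &
    ev$t_disappear_s <= t_new + 1e-9
  for (i in which(landing)) {
    hit <- catch_test(paddle_x, log$game$paddle_width_pct,
                      ev$x_spawn_pct[i], log$game$target_width_pct)
    if (ev$kind[i] == "target") {
      log$catches$caught[log$catches$event_id == ev$event_id[i]] <- hit
    } else {
      log$annotations$distractor_contact[
        log$annotations$event_id == ev$event_id[i]] <- hit
    }
  }
  log
}

# Build the intended (noise-free) paddle series for a kinematic player:
# sequential response plans, each holding its final position until the
# next target appears. Consumes RNG in event order.
intended_paddle <- function(player, events, t, initial_x) {
  x <- rep(initial_x, length(t))
  tgt <- events[events$kind == "target", , drop = FALSE]
  for (i in seq_len(nrow(tgt))) {
    ev <- tgt[i, ]
    before <- which(t < ev$t_appear_s - 1e-9)
    start_x <- if (length(before)) x[max(before)] else initial_x
    idx <- which(t >= ev$t_appear_s - 1e-9)
    if (!length(idx)) break
    plan <- plan_response(player, ev$x_spawn_pct - start_x,
                          ev$t_disappear_s - ev$t_appear_s)
    x[idx] <- eval_plan(plan, t[idx] - ev$t_appear_s, start_x)
  }
  x
}

# Low-pass (8 Hz, first-order) filtered white tremor with stationary sd
# `sd_target`. Consumes RNG.
tremor_series <- function(n, sd_target, frame_rate) {
  if (sd_target <= 0) return(rep(0, n))
  a <- exp(-2 * pi * 8 / frame_rate)
  innov_sd <- sd_target * sqrt(1 - a^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                           method = "recursive"))
}

#' Run a full game session
#'
#' Composes the scheduler, the virtual player and the frame stepper into
#' one deterministic session: given identical configs (including the seed
#' in the game config) two runs produce identical logs. In the default
#' kinematic mode the player commands paddle positions directly; in
#' torque mode the player's intended positions are tracked through the
#' device dynamics by a proportional-derivative controller, so the force
#' field and handle inertia shape the realised paddle path.
#'
#' @param device an [device_config()] (required for torque mode, optional
#'   metadata otherwise).
#' @param game an [game_config()] object.
#' @param player an [player_model()] or [player_preset()] object.
#' @param initial_paddle_x starting paddle position, percent (default 50).
#' @return an `rtp_session_log` with all frames, events, catch flags and
#'   config snapshots.
#' @export
run_session <- function(device = NULL, game = game_config(),
                        player = player_preset("able_bodied"),
                        initial_paddle_x = 50) {
  stopifnot(inherits(game, "rtp_game_config"), inherits(player, "rtp_player"))
  if (player$mode == "torque" && is.null(device)) {
    stop_rtp("torque mode requires a device config")
  }
  with_seed(game$seed, {
    events <- schedule_events(game, initial_paddle_x)
    dt <- 1 / game$frame_rate_hz
    nfr <- round(game$session_duration_s * game$frame_rate_hz)
    t <- (0:nfr) * dt
    x_int <- intended_paddle(player, events, t, initial_paddle_x)
    x_int <- x_int + tremor_series(length(t), player$tremor_sd,
                                   game$frame_rate_hz)
    half_pw <- game$paddle_width_pct / 2
    if (player$mode == "torque") {
      paddle <- track_through_device(x_int, device, dt)
    } else {
      paddle <- x_int
    }
    paddle <- clamp(paddle, half_pw, 100 - half_pw)

    log <- empty_session_log(game, events, device = device,
                             player = unclass(player), seed = game$seed)
    log$frames <- data.frame(t_s = t, paddle_x_pct = paddle)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      li <- findInterval(ev$t_disappear_s + 1e-9, t)
      li <- min(max(li, 1L), length(t))
      hit <- catch_test(paddle[li], game$paddle_width_pct,
                        ev$x_spawn_pct, game$target_width_pct)
      if (ev$kind == "target") {
        log$catches$caught[log$catches$event_id == ev$event_id] <- hit
      } else {
        log$annotations$distractor_contact[
          log$annotations$event_id == ev$event_id] <- hit
      }
    }
    log
  })
}

# PD tracking of an intended screen trajectory through the handle
# dynamics; gains are internal tuning constants of the torque mode.
track_through_device <- function(x_int, device, dt,
                                 kp = 4, kd = 0.08) {
  theta_des <- screen_to_angle(x_int, device)
  st <- device_state(theta = theta_des[1L])
  out <- numeric(length(x_int))
  out[1L] <- angle_to_screen(st$theta, device)
  for (k in 2:length(x_int)) {
    tau <- kp * (theta_des[k] - st$theta) - kd * st$omega
    st <- step_dynamics(st, tau, device, dt)
    out[k] <- angle_to_screen(st$theta, device)
  }
  out
}

#' @export
print.rtp_session_log <- function(x, ...) {
  nt <- sum(x$events$kind == "target")
  nd <- sum(x$events$kind == "distractor")
  cat("<rtp_session_log>\n")
  cat(sprintf("  %d frames at %g Hz, %d target events, %d distractors\n",
              nrow(x$frames), x$game$frame_rate_hz, nt, nd))
  if (nt > 0) {
    cat(sprintf("  caught %d/%d (%.1f%%)\n", sum(x$catches$caught), nt,
                100 * mean(x$catches$caught)))
  }
  invisible(x)
}
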
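# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive behaviour with different algorithms than
# the package (RK4 vs closed-form step, exhaustive scan vs run-length
# onset search) so agreement is informative.

# Classical fixed-step RK4 on the handle ODE
#   dtheta/dt = omega,  domega/dt = 1000 * (tau(t) - b*omega) / I
# (radians internally, degrees at the interface). No hard stops: oracle
# cases are chosen to stay inside the working range.
rk4_reference <- function(config, torque_fn, duration, dt,
                          theta0_deg, omega0_deg = 0) {
  I <- config$inertia_kgmm2
  b <- config$damping_Nmm_s_per_rad
  field <- switch(config$force_direction,
                  off = 0,
                  toward_max = config$force_magnitude_Nmm,
                  toward_min = -config$force_magnitude_Nmm)
  deriv <- function(t, y) {
    tau <- torque_fn(t) + field
    c(y[2], 1000 * (tau - b * y[2]) / I)
  }
  n <- round(duration / dt)
  y <- c(theta0_deg * pi / 180, omega0_deg * pi / 180)
  t <- 0
  out <- matrix(NA_real_, n + 1L, 3L)
  out[1L, ] <- c(t, y * 180 / pi)
  for (k in seq_len(n)) {
    k1 <- deriv(t, y)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    out[k + 1L, ] <- c(t, y * 180 / pi)
  }
  colnames(out) <- c("t", "theta", "omega")
  as.data.frame(out)
}

# Exhaustive onset scan: for every sample i with |d| >= thr, check that
# every sample within [t_i, t_i + hold] (clipped at the trace end) also
# satisfies the threshold; return the earliest such t_i.
brute_onset <- function(trace, thr, hold) {
  s <- trace$samples
  n <- nrow(s)
  for (i in seq_len(n)) {
    if (abs(s$displacement[i]) < thr) next
    win <- which(s$t >= s$t[i] - 1e-12 & s$t <= s$t[i] + hold + 1e-12)
    if (all(abs(s$displacement[win]) >= thr)) return(s$t[i])
  }
  NA_real_
}

# Build a trace object from raw vectors.
make_trace <- function(t, displacement, direction = "rightward",
                       caught = TRUE, required_amplitude = NA_real_,
                       event_id = 1L) {
  structure(list(event_id = event_id, direction = direction,
                 caught = caught,
                 required_amplitude = required_amplitude,
                 samples = data.frame(t = t, displacement = displacement)),
            class = "rtp_trace")
}

# Random piecewise-constant-plus-ramp trace with noise; exercises onset
# edge cases (threshold grazing, short bursts, late onsets, no onset).
random_trace <- function() {
  fr <- sample(c(30, 60, 120), 1L)
  dur <- stats::runif(1, 0.5, 2)
  t <- seq(0, dur, by = 1 / fr)
  kind <- sample(3L, 1L)
  d <- if (kind == 1L) {
    rep(0, length(t))                                  # no movement
  } else if (kind == 2L) {
    onset <- stats::runif(1, 0, dur * 0.8)
    amp <- stats::runif(1, 1, 30) * sample(c(-1, 1), 1L)
    amp * pmin(pmax((t - onset) / max(dur * 0.2, 0.05), 0), 1)
  } else {
    stats::runif(1, 0.5, 4) * sin(2 * pi * stats::runif(1, 0.5, 3) * t)
  }
  d <- d + stats::rnorm(length(t), 0, stats::runif(1, 0, 1))
  d[1L] <- 0
  make_trace(t, d)
}

# Hand-built session log: piecewise-linear paddle, explicit events.
# Used as a fixture whose metrics are computed by hand in the tests.
hand_log <- function() {
  game <- game_config(session_duration_s = 6, event_duration_s = 2,
                      paddle_width_pct = 10, target_width_pct = 5,
                      frame_rate_hz = 10, seed = 99L)
  events <- data.frame(
    event_id = 1:3, kind = "target",
    t_appear_s = c(0, 2, 4), t_disappear_s = c(2, 4, 6),
    x_spawn_pct = c(30, 70, 40),
    required_direction = c("leftward", "rightward", "leftward"),
    stringsAsFactors = FALSE)
  log <- empty_session_log(game, events, seed = 99L)
  t <- seq(0, 6, by = 0.1)
  # paddle: 50 -> 30 during event 1 (reach), hold; -> 70 during event 2;
  # stays at 70 for event 3 (no movement).
  x <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    x[i] <- if (ti <= 0.5) {
      50
    } else if (ti <= 1.5) {
      50 - 20 * (ti - 0.5)           # linear reach to 30
    } else if (ti <= 2.5) {
      30
    } else if (ti <= 3.5) {
      30 + 40 * (ti - 2.5)           # linear reach to 70
    } else {
      70
    }
  }
  log$frames <- data.frame(t_s = t, paddle_x_pct = x)
  log$catches$caught <- c(TRUE, TRUE, FALSE)
  log
}
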
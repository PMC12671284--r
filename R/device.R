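#' Configure the simulated manipulandum
#'
#' The device is a single-axis rotary handle whose shaft angle drives a
#' screen coordinate like a high-resolution mouse. Four user-facing
#' controls are modelled: gameplay orientation (which screen axis the
#' handle feeds), the working range of handle angles mapped onto the full
#' screen, an equivalent "sensitivity" parameterisation of that range, and
#' a unidirectional constant force field applied to the drive shaft
#' (assistive in one movement direction, resistive in the other).
#'
#' Exactly one of the working range (`theta_min_deg`/`theta_max_deg`) or
#' `sensitivity_deg_per_screen` drives the angle-to-screen mapping. A
#' sensitivity of `s` degrees-per-full-screen is converted internally to
#' the range `[-s/2, s/2]` centred on the neutral angle (0 degrees).
#'
#' @param orientation `"horizontal"` or `"vertical"` gameplay axis. The
#'   mapping mathematics are axis-agnostic; the orientation is carried in
#'   the log metadata only.
#' @param theta_min_deg,theta_max_deg working-range endpoints in degrees
#'   (`theta_max_deg > theta_min_deg`). Default 0 to 30, e.g. wrist
#'   neutral to 30 degrees of extension.
#' @param sensitivity_deg_per_screen alternative to an explicit range:
#'   degrees of handle rotation needed to traverse the full screen.
#' @param force_direction `"off"` (default), `"toward_min"` or
#'   `"toward_max"`: direction of the constant field torque.
#' @param force_magnitude_Nmm field torque magnitude, N*mm (>= 0).
#' @param inertia_kgmm2 handle + shaft rotary inertia, kg*mm^2 (> 0).
#' @param damping_Nmm_s_per_rad viscous damping, N*mm*s/rad (>= 0).
#'   Inertia and damping defaults are placeholders for a small printed
#'   handle; the mapping functions do not depend on them.
#' @return an object of class `rtp_device_config`.
#' @export
#' @examples
#' cfg <- device_config(theta_min_deg = 0, theta_max_deg = 30)
#' angle_to_screen(c(0, 10, 15, 30), cfg)
device_config <- function(orientation = "horizontal",
                          theta_min_deg = NULL,
                          theta_max_deg = NULL,
                          sensitivity_deg_per_screen = NULL,
                          force_direction = "off",
                          force_magnitude_Nmm = 0,
                          inertia_kgmm2 = 50,
                          damping_Nmm_s_per_rad = 5) {
  check_choice(orientation, "orientation", c("horizontal", "vertical"))
  check_choice(force_direction, "force_direction",
               c("toward_min", "toward_max", "off"))
  have_range <- !is.null(theta_min_deg) || !is.null(theta_max_deg)
  have_sens <- !is.null(sensitivity_deg_per_screen)
  if (have_range && have_sens) {
    stop_rtp("give either a working range or a sensitivity, not both",
             class = "rtp_config_error")
  }
  if (have_sens) {
    check_number(sensitivity_deg_per_screen, "sensitivity_deg_per_screen",
                 lo = .Machine$double.eps)
    theta_min_deg <- -sensitivity_deg_per_screen / 2
    theta_max_deg <- sensitivity_deg_per_screen / 2
  } else {
    theta_min_deg <- theta_min_deg %||% 0
    theta_max_deg <- theta_max_deg %||% 30
  }
  check_number(theta_min_deg, "theta_min_deg")
  check_number(theta_max_deg, "theta_max_deg")
  if (theta_max_deg <= theta_min_deg) {
    stop_rtp("degenerate working range: theta_max_deg must exceed theta_min_deg",
             class = "rtp_config_error")
  }
  check_number(force_magnitude_Nmm, "force_magnitude_Nmm", lo = 0)
  check_number(inertia_kgmm2, "inertia_kgmm2", lo = .Machine$double.eps)
  check_number(damping_Nmm_s_per_rad, "damping_Nmm_s_per_rad", lo = 0)
  structure(
    list(orientation = orientation,
         theta_min_deg = theta_min_deg,
         theta_max_deg = theta_max_deg,
         sensitivity_deg_per_screen = sensitivity_deg_per_screen,
         force_direction = force_direction,
         force_magnitude_Nmm = force_magnitude_Nmm,
         inertia_kgmm2 = inertia_kgmm2,
         damping_Nmm_s_per_rad = damping_Nmm_s_per_rad),
    class = "rtp_device_config")
}

#' @export
print.rtp_device_config <- function(x, ...) {
  cat("<rtp_device_config>\n")
  cat(sprintf("  orientation: %s\n", x$orientation))
  cat(sprintf("  working range: [%g, %g] deg\n", x$theta_min_deg, x$theta_max_deg))
  cat(sprintf("  force field: %s, %g N*mm\n", x$force_direction,
              x$force_magnitude_Nmm))
  cat(sprintf("  inertia %g kg*mm^2, damping %g N*mm*s/rad\n",
              x$inertia_kgmm2, x$damping_Nmm_s_per_rad))
  invisible(x)
}

#' Map a handle angle to a screen position
#'
#' Linear map of the working range `[theta_min, theta_max]` onto
#' `[0, 100]` percent of the screen; angles outside the working range
#' clamp to the nearest endpoint.
#'
#' @param theta handle angle(s), degrees.
#' @param config an [device_config()] object.
#' @return screen position(s), percent of screen width in `[0, 100]`.
#' @seealso [screen_to_angle()] for the inverse inside the range.
#' @export
angle_to_screen <- function(theta, config) {
  stopifnot(inherits(config, "rtp_device_config"))
  span <- config$theta_max_deg - config$theta_min_deg
  clamp((theta - config$theta_min_deg) / span * 100, 0, 100)
}

#' Map a screen position back to a handle angle
#'
#' Inverse of [angle_to_screen()] on `[0, 100]`; exact (to rounding) for
#' angles inside the working range.
#'
#' @param screen_pos screen position(s), percent in `[0, 100]`.
#' @inheritParams angle_to_screen
#' @return handle angle(s), degrees.
#' @export
screen_to_angle <- function(screen_pos, config) {
  stopifnot(inherits(config, "rtp_device_config"))
  span <- config$theta_max_deg - config$theta_min_deg
  config$theta_min_deg + clamp(screen_pos, 0, 100) / 100 * span
}

#' Create a device state
#'
#' @param theta handle angle, degrees.
#' @param omega angular velocity, degrees/s.
#' @param t time, seconds.
#' @return an object of class `rtp_device_state`.
#' @export
device_state <- function(theta = 0, omega = 0, t = 0) {
  check_number(theta, "theta")
  check_number(omega, "omega")
  check_number(t, "t", lo = 0)
  structure(list(theta = theta, omega = omega, t = t),
            class = "rtp_device_state")
}

# Field torque in N*mm, signed toward increasing theta.
field_torque <- function(config) {
  switch(config$force_direction,
         off = 0,
         toward_max = config$force_magnitude_Nmm,
         toward_min = -config$force_magnitude_Nmm)
}

#' Advance the handle dynamics one step
#'
#' Integrates the rotary dynamics `I * alpha = tau_player + tau_field -
#' b * omega` over one step of length `dt`, holding the applied torque
#' constant across the step. Because the damped constant-torque system is
#' linear, the step uses the exact exponential solution (closed form),
#' which is unconditionally stable and agrees with a fine-step reference
#' integration to numerical precision. The field torque is constant toward
#' its configured direction regardless of motion direction, so it assists
#' one movement direction and resists the other. The working-range limits
#' act as hard stops: the angle clamps and the velocity resets to zero.
#'
#' Units: torques in N*mm, inertia in kg*mm^2, damping in N*mm*s/rad;
#' in this millimetre-based system `alpha[rad/s^2] = 1000 * tau / I`.
#'
#' @param state an [device_state()] object.
#' @param player_torque torque applied by the player, N*mm (finite).
#' @param config an [device_config()] object.
#' @param dt step length, seconds (> 0).
#' @return the updated `rtp_device_state`.
#' @export
step_dynamics <- function(state, player_torque, config, dt) {
  stopifnot(inherits(state, "rtp_device_state"),
            inherits(config, "rtp_device_config"))
  if (!is.numeric(player_torque) || length(player_torque) != 1L ||
      !is.finite(player_torque)) {
    stop_rtp("player_torque must be a single finite number")
  }
  check_number(dt, "dt", lo = .Machine$double.xmin)

  tau <- player_torque + field_torque(config)   # N*mm, constant over step
  I <- config$inertia_kgmm2
  b <- config$damping_Nmm_s_per_rad
  deg <- 180 / pi
  th0 <- state$theta / deg                       # rad
  w0 <- state$omega / deg                        # rad/s

  if (b > 0) {
    lambda <- 1000 * b / I                       # 1/s
    w_ss <- tau / b                              # rad/s
    e <- exp(-lambda * dt)
    w1 <- w_ss + (w0 - w_ss) * e
    th1 <- th0 + w_ss * dt + (w0 - w_ss) * (1 - e) / lambda
  } else {
    a <- 1000 * tau / I                          # rad/s^2
    w1 <- w0 + a * dt
    th1 <- th0 + w0 * dt + 0.5 * a * dt^2
  }

  theta <- th1 * deg
  omega <- w1 * deg
  if (theta <= config$theta_min_deg) {
    theta <- config$theta_min_deg
    omega <- 0
  } else if (theta >= config$theta_max_deg) {
    theta <- config$theta_max_deg
    omega <- 0
  }
  device_state(theta = theta, omega = omega, t = state$t + dt)
}

#' Simulate the handle under a torque profile
#'
#' Convenience wrapper repeatedly applying [step_dynamics()].
#'
#' @param config an [device_config()] object.
#' @param torque_fn function of time (s) returning player torque (N*mm).
#' @param duration total simulated time, seconds.
#' @param dt step, seconds (default 1/120, the game frame period).
#' @param state initial state (default: at rest at the range midpoint).
#' @return data.frame with columns `t`, `theta`, `omega`.
#' @export
simulate_device <- function(config, torque_fn, duration, dt = 1 / 120,
                            state = NULL) {
  stopifnot(is.function(torque_fn))
  if (is.null(state)) {
    state <- device_state(
      theta = (config$theta_min_deg + config$theta_max_deg) / 2)
  }
  n <- floor(duration / dt + 1e-9)
  out <- data.frame(t = numeric(n + 1L), theta = numeric(n + 1L),
                    omega = numeric(n + 1L))
  out[1L, ] <- c(state$t, state$theta, state$omega)
  for (k in seq_len(n)) {
    state <- step_dynamics(state, torque_fn(state$t), config, dt)
    out[k + 1L, ] <- c(state$t, state$theta, state$omega)
  }
  out
}
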
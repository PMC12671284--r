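test_that("segmentation yields one trace per target with zeroed origin", {
  log <- run_session(game = game_config(seed = 2),
                     player = player_preset("stroke_mild"))
  traces <- segment_responses(log)
  expect_length(traces, 30L)
  for (tr in traces[c(1, 15, 30)]) {
    expect_equal(tr$samples$displacement[1], 0)
    expect_equal(tr$samples$t[1], 0)
    expect_equal(max(tr$samples$t), 2, tolerance = 1e-9)
  }
  # sign convention: displacement toward the target is positive
  finals <- vapply(traces, function(tr) {
    tail(tr$samples$displacement, 1)
  }, numeric(1))
  expect_true(mean(finals > 0) > 0.9)
})

test_that("segmentation matches hand-extracted slices on a built log", {
  log <- hand_log()
  traces <- segment_responses(log)
  expect_length(traces, 3L)
  # event 1: leftward, so displacement = 50 - paddle
  tr1 <- traces[[1]]
  expect_equal(tr1$direction, "leftward")
  expect_equal(tr1$required_amplitude, 20)
  expect_equal(tr1$samples$displacement[tr1$samples$t == 1.5], 20)
  expect_equal(tr1$samples$displacement[tr1$samples$t == 0.5], 0)
  # event 2: rightward from 30 to 70
  tr2 <- traces[[2]]
  expect_equal(tr2$required_amplitude, 40)
  expect_equal(tr2$samples$displacement, pmin(pmax(
    40 * (tr2$samples$t - 0.5), 0), 40), tolerance = 1e-9)
  # event 3: no movement
  expect_true(all(traces[[3]]$samples$displacement == 0))
})

test_that("segmentation errors on logs with missing frames", {
  log <- hand_log()
  log$frames <- log$frames[-(12:15), ]    # hole inside event 1
  expect_error(segment_responses(log), "event 1")
})

test_that("detect_onset handles canonical cases", {
  t <- seq(0, 2, by = 0.01)
  flat <- make_trace(t, rep(0, length(t)))
  expect_true(is.na(detect_onset(flat)))
  step <- make_trace(t, ifelse(t >= 0.4, 10, 0))
  expect_equal(detect_onset(step, 2, 0.05), 0.4)
  # a burst shorter than min_hold is rejected
  burst <- make_trace(t, ifelse(t >= 0.4 & t < 0.43, 10, 0))
  expect_true(is.na(detect_onset(burst, 2, 0.05)))
  # negative-going movement triggers on |displacement|
  neg <- make_trace(t, ifelse(t >= 0.7, -10, 0))
  expect_equal(detect_onset(neg, 2, 0.05), 0.7)
})

test_that("detect_onset agrees with the exhaustive scan oracle", {
  set.seed(123)
  for (i in 1:200) {
    tr <- random_trace()
    thr <- stats::runif(1, 0.5, 5)
    hold <- stats::runif(1, 0.02, 0.2)
    expect_identical(detect_onset(tr, thr, hold),
                     brute_onset(tr, thr, hold))
  }
})

test_that("success_rate averages directions unweighted", {
  mk <- function(dir, caught) {
    make_trace(c(0, 1), c(0, 0), direction = dir, caught = caught)
  }
  all_caught <- structure(c(lapply(1:3, function(i) mk("leftward", TRUE)),
                            lapply(1:3, function(i) mk("rightward", TRUE))),
                          class = "rtp_traces")
  expect_equal(success_rate(all_caught)$SR_avg, 100)
  half <- structure(c(lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                             function(cg) mk("leftward", cg)),
                      lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                             function(cg) mk("rightward", cg))),
                    class = "rtp_traces")
  expect_equal(success_rate(half)$SR_avg, 50)
  # left 40%, right 60% -> unweighted 50 despite unequal counts
  lr <- structure(c(lapply(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                           function(cg) mk("leftward", cg)),
                    lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                           function(cg) mk("rightward", cg))),
                  class = "rtp_traces")
  out <- success_rate(lr)
  expect_equal(out$SR_left, 40)
  expect_equal(out$SR_right, 60)
  expect_equal(out$SR_avg, 50)
  # single-direction fallback warns
  only_l <- structure(lapply(c(TRUE, FALSE), function(cg)
    mk("leftward", cg)), class = "rtp_traces")
  expect_warning(out2 <- success_rate(only_l), "one movement direction")
  expect_equal(out2$SR_avg, 50)
})

test_that("trace_kinematics quantifies accuracy and overshoot", {
  t <- seq(0, 2, by = 1 / 120)
  # clean minimum-jerk reach exactly to a 30% target
  d <- ifelse(t < 1, minimum_jerk(0, 30, 1, pmin(t, 1)), 30)
  tr <- make_trace(t, d, required_amplitude = 30)
  k <- trace_kinematics(tr)
  expect_equal(k$overshoot_count, 0)
  expect_equal(k$final_error, 0)
  expect_equal(k$peak_amplitude, 30)
  # reach to 120% then settle back at 100%
  d2 <- ifelse(t < 1, minimum_jerk(0, 36, 1, pmin(t, 1)),
               ifelse(t < 1.5,
                      minimum_jerk(36, 30, 0.5, pmax(pmin(t - 1, 0.5), 0)),
                      30))
  k2 <- trace_kinematics(make_trace(t, d2, required_amplitude = 30))
  expect_equal(k2$overshoot_count, 1)
  expect_equal(k2$final_error, 0)
  expect_equal(k2$peak_amplitude, 36)
  # no onset -> all absent
  k3 <- trace_kinematics(make_trace(t, rep(0, length(t))))
  expect_true(all(is.na(unlist(k3))))
})

test_that("stroke players overshoot more than able-bodied ones", {
  mean_overshoot <- function(profile) {
    mean(vapply(1:10, function(s) {
      log <- run_session(game = game_config(seed = s),
                         player = player_preset(profile))
      session_summary(log)$overshoot_count_mean
    }, numeric(1)))
  }
  expect_gt(mean_overshoot("stroke_moderate"),
            mean_overshoot("able_bodied"))
})

test_that("raw variability matches its closed form on constant traces", {
  t <- seq(0, 2, by = 0.1)
  a <- make_trace(t, rep(0, length(t)))
  b <- make_trace(t, rep(10, length(t)))
  same <- structure(list(a, a, a), class = "rtp_traces")
  expect_equal(movement_variability(same), 0)
  two <- structure(list(a, b), class = "rtp_traces")
  expect_equal(movement_variability(two), stats::sd(c(0, 10)),
               tolerance = 1e-12)
  expect_warning(v <- movement_variability(structure(list(a),
                                                     class = "rtp_traces")),
                 "fewer than 2")
  expect_true(is.na(v))
})

test_that("movement-normalized variability separates phenotypes", {
  mean_var <- function(profile) {
    mean(vapply(1:10, function(s) {
      log <- run_session(game = game_config(seed = s),
                         player = player_preset(profile))
      session_summary(log)$variability
    }, numeric(1)))
  }
  expect_lt(mean_var("able_bodied"), mean_var("stroke_severe"))
})

test_that("session_summary composes the per-session report", {
  log <- hand_log()
  m <- session_summary(log)
  expect_equal(m$SR_left, 50)
  expect_equal(m$SR_right, 100)
  expect_equal(m$SR_avg, 75)
  expect_equal(m$MOT_left_mean, 0.6)
  expect_equal(m$MOT_right_mean, 0.6)
  expect_equal(m$MOT_avg, 0.6)
  expect_equal(m$response_time_ms, 600)
  expect_equal(m$movement_duration_mean, 0.9, tolerance = 1e-9)
  expect_equal(m$peak_amplitude_mean, 30)
  expect_equal(m$overshoot_count_mean, 0)
  expect_equal(m$final_error_mean, 0)
  expect_equal(m$n_left, 2L)
  expect_equal(m$n_right, 1L)
})

test_that("SR from traces equals SR from engine catch flags", {
  for (s in c(3, 14)) {
    log <- run_session(game = game_config(seed = s),
                       player = player_preset("stroke_moderate"))
    traces <- segment_responses(log)
    expect_equal(mean(vapply(traces, `[[`, logical(1), "caught")),
                 mean(log$catches$caught))
  }
})

test_that("metrics are invariant to added distractor events", {
  log <- run_session(game = game_config(seed = 9),
                     player = player_preset("stroke_mild"))
  base <- session_summary(log)
  with_d <- log
  nd <- 5L
  with_d$events <- rbind(with_d$events, data.frame(
    event_id = 30L + seq_len(nd), kind = "distractor",
    t_appear_s = seq(0, 8, by = 2), t_disappear_s = seq(2, 10, by = 2),
    x_spawn_pct = rep(20, nd), required_direction = NA_character_))
  with_d$annotations <- data.frame(event_id = 30L + seq_len(nd),
                                   distractor_contact = FALSE)
  expect_equal(unclass(session_summary(with_d)), unclass(base))
})

test_that("ideal-player summary recovers the configured behaviour", {
  ideal <- player_model(onset_latency_mean = 0, onset_latency_sd = 0,
                        movement_time_per_amplitude = 0.005,
                        tremor_sd = 0, submovement_prob = 0)
  log <- run_session(game = game_config(seed = 17), player = ideal)
  m <- session_summary(log)
  expect_equal(m$SR_avg, 100)
  # MOT = configured (zero) latency plus the small threshold-crossing lag
  expect_lt(m$MOT_avg, 0.06)
  # final error is not exactly zero: the paddle centre is clamped to
  # [pw/2, 100 - pw/2] while spawns may sit slightly outside that band
  expect_lt(m$final_error_mean, 0.5)
})

test_that("overlay export flattens traces with their metadata", {
  log <- hand_log()
  ov <- overlay_data(segment_responses(log))
  expect_equal(sort(unique(ov$event_id)), 1:3)
  expect_equal(nrow(ov), 3 * 21)
  expect_true(all(c("direction", "caught", "t_s", "displacement_pct")
                  %in% names(ov)))
})
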
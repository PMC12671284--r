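test_that("scheduler fills the session with back-to-back balanced events", {
  g <- game_config(session_duration_s = 60, event_duration_s = 2, seed = 1)
  ev <- withr::with_seed(1, schedule_events(g))
  expect_equal(nrow(ev), 30L)
  expect_equal(sum(ev$required_direction == "leftward"), 15L)
  expect_equal(sum(ev$required_direction == "rightward"), 15L)
  # back-to-back, non-overlapping
  expect_equal(ev$t_appear_s[-1], ev$t_disappear_s[-30], tolerance = 1e-12)
  expect_equal(ev$t_disappear_s - ev$t_appear_s, rep(2, 30))
  # spawns inside the feasible strip
  w2 <- g$target_width_pct / 2
  expect_true(all(ev$x_spawn_pct >= w2 & ev$x_spawn_pct <= 100 - w2))
  # single-slot session
  g1 <- game_config(session_duration_s = 2, event_duration_s = 2)
  expect_equal(nrow(withr::with_seed(1, schedule_events(g1))), 1L)
})

test_that("scheduler warns and returns empty for a too-short session", {
  g <- game_config(session_duration_s = 1, event_duration_s = 2)
  expect_warning(ev <- schedule_events(g), "shorter than one event")
  expect_equal(nrow(ev), 0L)
})

test_that("spawns fall on the required side of the expected paddle", {
  g <- game_config(seed = 5)
  ev <- withr::with_seed(5, schedule_events(g, initial_paddle_x = 50))
  ref <- c(50, ev$x_spawn_pct[-nrow(ev)])
  left <- ev$required_direction == "leftward"
  expect_true(all(ev$x_spawn_pct[left] < ref[left]))
  expect_true(all(ev$x_spawn_pct[!left] > ref[!left]))
})

test_that("direction balance holds within 1 for odd counts and all seeds", {
  g <- game_config(session_duration_s = 14, event_duration_s = 2)
  for (s in 1:30) {
    ev <- withr::with_seed(s, schedule_events(g))
    expect_equal(nrow(ev), 7L)
    expect_lte(abs(sum(ev$required_direction == "leftward") -
                     sum(ev$required_direction == "rightward")), 1L)
  }
})

test_that("catch_test implements the closed overlap rule", {
  expect_true(catch_test(50, 10, 50, 5))
  expect_false(catch_test(10, 5, 90, 5))
  # boundary: separation exactly equal to half-width sum counts
  expect_true(catch_test(50, 10, 57.5, 5))
  expect_false(catch_test(50, 10, 57.6, 5))
  expect_true(catch_test(50, 10, 42.5, 5))
})

test_that("game_step appends frames and resolves catches at landing", {
  g <- game_config(session_duration_s = 4, event_duration_s = 2,
                   frame_rate_hz = 10, seed = 3)
  ev <- data.frame(event_id = 1:2, kind = "target",
                   t_appear_s = c(0, 2), t_disappear_s = c(2, 4),
                   x_spawn_pct = c(30, 80),
                   required_direction = c("leftward", "rightward"))
  log <- empty_session_log(g, ev)
  expect_error(game_step(log, 50, 0.5), "1/frame_rate")
  log <- game_step(log, 50, 0.1)
  expect_equal(nrow(log$frames), 1L)
  expect_true(all(is.na(log$catches$caught)))
  # step to t = 2: first target lands; paddle sits on it
  for (k in 1:20) log <- game_step(log, 30, 0.1)
  expect_true(log$catches$caught[1])
  expect_true(is.na(log$catches$caught[2]))
  # step to t = 4 with paddle far away: second target missed
  for (k in 1:20) log <- game_step(log, 30, 0.1)
  expect_false(log$catches$caught[2])
})

test_that("incremental stepping reproduces run_session catches", {
  g <- game_config(session_duration_s = 10, event_duration_s = 2,
                   frame_rate_hz = 30, seed = 11)
  log <- run_session(game = g, player = player_preset("stroke_moderate"))
  replay <- empty_session_log(g, log$events)
  replay$frames <- log$frames[0, ]
  for (i in seq_len(nrow(log$frames))) {
    replay <- game_step(replay, log$frames$paddle_x_pct[i], 1 / 30)
  }
  expect_equal(replay$catches$caught, log$catches$caught)
  expect_equal(replay$frames$t_s, log$frames$t_s, tolerance = 1e-9)
})

test_that("run_session is deterministic and complete", {
  g <- game_config(session_duration_s = 20, seed = 42)
  l1 <- run_session(game = g, player = player_preset("stroke_mild"))
  l2 <- run_session(game = g, player = player_preset("stroke_mild"))
  expect_identical(l1, l2)
  expect_equal(nrow(l1$frames), 20 * 120 + 1)
  expect_equal(nrow(l1$catches), sum(l1$events$kind == "target"))
  expect_true(all(!is.na(l1$catches$caught)))
})

test_that("ideal tracking catches everything; a frozen paddle nothing", {
  ideal <- player_model(onset_latency_mean = 0, onset_latency_sd = 0,
                        amplitude_gain = 1,
                        movement_time_per_amplitude = 0.005,
                        tremor_sd = 0, submovement_prob = 0)
  g <- game_config(session_duration_s = 30, seed = 8)
  log <- run_session(game = g, player = ideal)
  expect_equal(mean(log$catches$caught), 1)
  # frozen paddle: replay the schedule with the paddle pinned at centre.
  # Only targets that happen to spawn within the overlap tolerance of 50
  # can be caught (spawns are placed relative to the *previous* spawn, so
  # some may still fall near centre); all off-paddle targets are missed.
  frozen <- empty_session_log(g, log$events)
  for (k in 0:(30 * 120)) frozen <- game_step(frozen, 50, 1 / 120)
  tol <- (g$paddle_width_pct + g$target_width_pct) / 2
  expect_equal(frozen$catches$caught,
               abs(log$events$x_spawn_pct - 50) <= tol)
  expect_false(all(frozen$catches$caught))
})

test_that("distractors are logged and annotated but never scored", {
  g <- game_config(session_duration_s = 20, distractors_enabled = TRUE,
                   distractors_per_event = 1L, seed = 21)
  log <- run_session(game = g, player = player_preset("stroke_moderate"))
  nt <- sum(log$events$kind == "target")
  nd <- sum(log$events$kind == "distractor")
  expect_equal(nt, 10L)
  expect_equal(nd, 10L)
  expect_equal(nrow(log$catches), nt)
  expect_equal(nrow(log$annotations), nd)
  expect_false(any(log$events$event_id[log$events$kind == "distractor"]
                   %in% log$catches$event_id))
})

test_that("objects descend strictly monotonically from 100 to 0", {
  y <- rtpgame:::object_y(seq(1, 3, by = 0.05), 1, 3)
  expect_equal(y[1], 100)
  expect_equal(y[length(y)], 0)
  expect_true(all(diff(y) < 0))
})
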
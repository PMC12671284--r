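#' Write a session log to disk
#'
#' Serialises a session log as a frames CSV plus a JSON sidecar. The CSV
#' (`<prefix>_frames.csv`) is in long format, one row per frame and
#' active object with columns `t_s, paddle_x_pct, event_id, object_kind,
#' object_x_pct, object_y_pct` (object columns empty for frames with no
#' active object); object vertical positions descend linearly from 100 to
#' 0 over the event window. The sidecar (`<prefix>_meta.json`) carries
#' the schema version, seed, config snapshots, event schedule, catch
#' flags and distractor annotations. The write/read round trip is
#' lossless for all fields (to floating-point text precision).
#'
#' @param log an `rtp_session_log`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
write_session_log <- function(log, prefix) {
  stopifnot(inherits(log, "rtp_session_log"))
  frames <- log$frames
  ev <- log$events
  rows <- list(data.frame(t_s = frames$t_s,
                          paddle_x_pct = frames$paddle_x_pct,
                          event_id = NA_integer_,
                          object_kind = NA_character_,
                          object_x_pct = NA_real_,
                          object_y_pct = NA_real_))
  for (i in seq_len(nrow(ev))) {
    idx <- which(frames$t_s >= ev$t_appear_s[i] - 1e-9 &
                   frames$t_s <= ev$t_disappear_s[i] + 1e-9)
    if (!length(idx)) next
    rows[[length(rows) + 1L]] <- data.frame(
      t_s = frames$t_s[idx], paddle_x_pct = frames$paddle_x_pct[idx],
      event_id = ev$event_id[i], object_kind = ev$kind[i],
      object_x_pct = ev$x_spawn_pct[i],
      object_y_pct = object_y(frames$t_s[idx], ev$t_appear_s[i],
                              ev$t_disappear_s[i]))
  }
  long <- do.call(rbind, rows)
  long <- long[order(long$t_s, long$event_id, na.last = FALSE), ]
  f_csv <- paste0(prefix, "_frames.csv")
  f_json <- paste0(prefix, "_meta.json")
  utils::write.csv(long, f_csv, row.names = FALSE, na = "")
  meta <- list(schema_version = log$schema_version,
               seed = log$seed,
               game = unclass(log$game),
               device = if (!is.null(log$device)) unclass(log$device),
               player = log$player,
               events = log$events,
               catches = log$catches,
               annotations = log$annotations)
  jsonlite::write_json(meta, f_json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(c(frames = f_csv, meta = f_json))
}

#' Read a session log from disk
#'
#' Rebuilds an `rtp_session_log` from the `<prefix>_frames.csv` +
#' `<prefix>_meta.json` pair written by [write_session_log()] (or
#' supplied externally in the same format).
#'
#' @param prefix path prefix used at write time.
#' @return an `rtp_session_log`.
#' @export
read_session_log <- function(prefix) {
  f_csv <- paste0(prefix, "_frames.csv")
  f_json <- paste0(prefix, "_meta.json")
  if (!file.exists(f_csv) || !file.exists(f_json)) {
    stop_rtp("no session log at prefix '", prefix,
             "': expected ", f_csv, " and ", f_json,
             class = "rtp_log_error")
  }
  long <- utils::read.csv(f_csv)
  need <- c("t_s", "paddle_x_pct", "event_id", "object_kind",
            "object_x_pct", "object_y_pct")
  if (!all(need %in% names(long))) {
    stop_rtp("malformed frames CSV: expected columns ",
             paste(need, collapse = ", "), class = "rtp_log_error")
  }
  meta <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  game <- do.call(game_config, meta$game[names(meta$game) %in%
                                           names(formals(game_config))])
  device <- if (!is.null(meta$device)) {
    do.call(device_config,
            meta$device[names(meta$device) %in%
                          names(formals(device_config))])
  }
  frames <- unique(long[, c("t_s", "paddle_x_pct")])
  frames <- frames[order(frames$t_s), ]
  rownames(frames) <- NULL
  ev <- meta$events
  log <- empty_session_log(game, ev, device = device,
                           player = meta$player,
                           seed = meta$seed %||% NA_integer_)
  log$frames <- frames
  if (is.data.frame(meta$catches) && nrow(meta$catches)) {
    log$catches <- meta$catches
  }
  if (is.data.frame(meta$annotations) && nrow(meta$annotations)) {
    log$annotations <- meta$annotations
  }
  log$schema_version <- meta$schema_version %||% 1L
  log
}

#' Read and validate a run configuration file
#'
#' One JSON file with optional sections `device`, `game`, `player` and
#' `metrics`, plus an optional top-level `seed` overriding the game
#' seed. Unknown sections or keys are rejected by name. The `player`
#' section is either `{"preset": "<name>"}` or a full set of
#' [player_model()] arguments.
#'
#' @param path path to the JSON config file.
#' @return list with validated `device`, `game`, `player` objects and a
#'   `metrics` list (`displacement_threshold`, `min_hold`, `stop_speed`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_rtp("config file not found: ", path, class = "rtp_config_error")
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_rtp("config file is not valid JSON: ",
                             conditionMessage(e),
                             class = "rtp_config_error")
                  })
  known <- c("device", "game", "player", "metrics", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop_rtp("unknown config section(s): ", paste(extra, collapse = ", "),
             class = "rtp_config_error")
  }
  section <- function(x, fn, what) {
    x <- as.list(x %||% list())
    bad <- setdiff(names(x), names(formals(fn)))
    if (length(bad)) {
      stop_rtp(sprintf("unknown key(s) in %s section: %s", what,
                       paste(bad, collapse = ", ")),
               class = "rtp_config_error")
    }
    do.call(fn, x)
  }
  device <- if (!is.null(raw$device)) section(raw$device, device_config,
                                              "device")
  pl <- as.list(raw$player %||% list())
  player <- if (!is.null(pl$preset)) {
    extra <- setdiff(names(pl), "preset")
    if (length(extra)) {
      stop_rtp("player preset cannot be combined with key(s): ",
               paste(extra, collapse = ", "), class = "rtp_config_error")
    }
    if (!pl$preset %in% c("able_bodied", "stroke_mild", "stroke_moderate",
                          "stroke_severe")) {
      stop_rtp("unknown player preset: ", pl$preset,
               class = "rtp_config_error")
    }
    player_preset(pl$preset)
  } else {
    section(pl, player_model, "player")
  }
  game <- section(raw$game, game_config, "game")
  if (!is.null(raw$seed)) {
    check_number(raw$seed, "seed")
    game$seed <- as.integer(raw$seed)
  }
  met <- as.list(raw$metrics %||% list())
  known_m <- c("displacement_threshold", "min_hold", "stop_speed")
  bad <- setdiff(names(met), known_m)
  if (length(bad)) {
    stop_rtp("unknown key(s) in metrics section: ",
             paste(bad, collapse = ", "), class = "rtp_config_error")
  }
  metrics <- list(displacement_threshold = met$displacement_threshold %||% 2,
                  min_hold = met$min_hold %||% 0.05,
                  stop_speed = met$stop_speed %||% 5)
  list(device = device, game = game, player = player, metrics = metrics)
}

#' Write session metrics as JSON and CSV
#'
#' @param metrics an `rtp_session_metrics` from [session_summary()].
#' @param prefix output path prefix; writes `<prefix>_metrics.json` and a
#'   one-row `<prefix>_metrics.csv`.
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(metrics, prefix) {
  stopifnot(inherits(metrics, "rtp_session_metrics"))
  f_json <- paste0(prefix, "_metrics.json")
  f_csv <- paste0(prefix, "_metrics.csv")
  jsonlite::write_json(unclass(metrics), f_json, auto_unbox = TRUE,
                       digits = NA, na = "null")
  utils::write.csv(as.data.frame(unclass(metrics)), f_csv,
                   row.names = FALSE)
  invisible(c(json = f_json, csv = f_csv))
}
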
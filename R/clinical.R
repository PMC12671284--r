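#' Create a Wolf Motor Function Test record
#'
#' One administration of the 15-task WMFT for one participant: per-task
#' completion time (capped at the 120 s limit) and per-task functional
#' ability score (FAS), an ordinal movement-quality grade from 0 (no
#' performance) to 5 (normal movement), giving a maximum summed FAS of 75.
#'
#' @param participant_id identifier (coerced to character).
#' @param task_times_s numeric vector of 15 task times, each in
#'   `[0, 120]` seconds.
#' @param fas_grades integer vector of 15 grades, each in 0..5.
#' @param phase `"pre"` or `"post"` intervention.
#' @return an object of class `rtp_wmft_record`.
#' @export
wmft_record <- function(participant_id, task_times_s, fas_grades,
                        phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (length(task_times_s) != 15L || length(fas_grades) != 15L) {
    stop_rtp("a WMFT record needs exactly 15 task times and 15 grades")
  }
  if (any(!is.finite(task_times_s)) || any(task_times_s < 0) ||
      any(task_times_s > 120)) {
    stop_rtp("task times must lie in [0, 120] seconds")
  }
  if (any(fas_grades != as.integer(fas_grades)) || any(fas_grades < 0) ||
      any(fas_grades > 5)) {
    stop_rtp("FAS grades must be integers in 0..5")
  }
  structure(list(participant_id = as.character(participant_id),
                 task_times_s = as.numeric(task_times_s),
                 fas_grades = as.integer(fas_grades),
                 phase = phase),
            class = "rtp_wmft_record")
}

#' Total WMFT scores
#'
#' The two summary scores of a WMFT administration: the summed
#' movement-quality grades of the 15 tasks (FAS total, maximum 75) and
#' the total time taken for the 15 tasks.
#'
#' @param record an [wmft_record()].
#' @return list with `FAS_total` (points) and `total_time` (s).
#' @export
wmft_totals <- function(record) {
  stopifnot(inherits(record, "rtp_wmft_record"))
  list(FAS_total = sum(record$fas_grades),
       total_time = sum(record$task_times_s))
}

#' Pre/post change scores
#'
#' Change is reported as improvement: FAS change is post minus pre
#' (positive = better movement quality); time change is pre minus post
#' (positive = faster).
#'
#' @param pre,post either [wmft_record()]s (totalled automatically) or
#'   lists with `FAS_total` and `total_time`, for the same participant.
#' @return list with `FAS_change` (points) and `time_change` (s).
#' @export
change_scores <- function(pre, post) {
  as_tot <- function(x) {
    if (inherits(x, "rtp_wmft_record")) wmft_totals(x) else x
  }
  if (inherits(pre, "rtp_wmft_record") && inherits(post, "rtp_wmft_record")) {
    if (pre$participant_id != post$participant_id) {
      stop_rtp("pre and post records belong to different participants")
    }
  }
  a <- as_tot(pre)
  b <- as_tot(post)
  list(FAS_change = b$FAS_total - a$FAS_total,
       time_change = a$total_time - b$total_time)
}

#' MCID thresholds for the WMFT
#'
#' Published minimal clinically important differences for the WMFT in
#' stroke: 3 to 6 FAS points (the conservative upper bound 6 is the
#' default) and 22 seconds of total time.
#'
#' @param fas_points FAS MCID, points (> 0; configurable over 3..6).
#' @param total_time_seconds total-time MCID, s (> 0; default 22).
#' @return an object of class `rtp_mcid_thresholds`.
#' @export
mcid_thresholds <- function(fas_points = 6, total_time_seconds = 22) {
  check_number(fas_points, "fas_points", lo = .Machine$double.xmin)
  check_number(total_time_seconds, "total_time_seconds",
               lo = .Machine$double.xmin)
  structure(list(fas_points = fas_points,
                 total_time_seconds = total_time_seconds),
            class = "rtp_mcid_thresholds")
}

#' Flag changes that surpass the MCID
#'
#' "Surpassed" is strict: a change exactly at the threshold does not
#' count.
#'
#' @param change list from [change_scores()] (`FAS_change`,
#'   `time_change`).
#' @param thresholds an [mcid_thresholds()] (default thresholds if
#'   omitted).
#' @return list with logical `fas_exceeds` and `time_exceeds`.
#' @export
mcid_flags <- function(change, thresholds = mcid_thresholds()) {
  stopifnot(inherits(thresholds, "rtp_mcid_thresholds"))
  list(fas_exceeds = change$FAS_change > thresholds$fas_points,
       time_exceeds = change$time_change > thresholds$total_time_seconds)
}

#' Group mean and sample SD with report rounding
#'
#' The "Average (SD)" cell of a report table: mean and sample standard
#' deviation (n - 1 denominator) of a vector, plus the values rounded
#' half-away-from-zero to integers and the rendered cell string.
#'
#' @param values numeric vector (n >= 2 for an SD; with n < 2 the SD is
#'   `NA`).
#' @param digits decimal places for the rendered cell (default 0,
#'   matching report tables).
#' @return list with `mean`, `sd`, `mean_rounded`, `sd_rounded`, `cell`.
#' @export
#' @examples
#' group_summary(c(9, 15, 14, 16, 14))$cell # "14 (3)"
group_summary <- function(values, digits = 0L) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  m <- mean(values)
  s <- if (length(values) >= 2L) stats::sd(values) else NA_real_
  mr <- round_half_up(m, digits)
  sr <- if (is.na(s)) NA_real_ else round_half_up(s, digits)
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  list(mean = m, sd = s, mean_rounded = mr, sd_rounded = sr,
       cell = if (is.na(sr)) fmt(mr) else sprintf("%s (%s)", fmt(mr),
                                                  fmt(sr)))
}

#' Summarise WMFT outcomes across participants
#'
#' Builds the pre/post/change WMFT outcome table from per-participant
#' totals: one row per participant plus an "Average (SD)" row per
#' column, with MCID flags on the change scores.
#'
#' @param wmft data.frame with columns `participant`, `fas_pre`,
#'   `fas_post`, `time_pre_s`, `time_post_s` (one row per participant).
#' @param thresholds an [mcid_thresholds()].
#' @return list with `table` (per-participant data.frame including
#'   changes and MCID flags), `summary` (named list of [group_summary()]
#'   results for the six columns) and `mcid_counts` (list `fas`, `time`).
#' @export
wmft_outcome_table <- function(wmft, thresholds = mcid_thresholds()) {
  need <- c("participant", "fas_pre", "fas_post", "time_pre_s",
            "time_post_s")
  if (!all(need %in% names(wmft))) {
    stop_rtp("wmft table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- wmft
  tab$fas_change <- tab$fas_post - tab$fas_pre
  tab$time_change_s <- tab$time_pre_s - tab$time_post_s
  flags <- mapply(function(fc, tc) {
    mcid_flags(list(FAS_change = fc, time_change = tc), thresholds)
  }, tab$fas_change, tab$time_change_s, SIMPLIFY = FALSE)
  tab$fas_exceeds_mcid <- vapply(flags, `[[`, logical(1), "fas_exceeds")
  tab$time_exceeds_mcid <- vapply(flags, `[[`, logical(1), "time_exceeds")
  summ <- list(fas_pre = group_summary(tab$fas_pre),
               fas_post = group_summary(tab$fas_post),
               fas_change = group_summary(tab$fas_change),
               time_pre = group_summary(tab$time_pre_s),
               time_post = group_summary(tab$time_post_s),
               time_change = group_summary(tab$time_change_s))
  list(table = tab, summary = summ,
       mcid_counts = list(fas = sum(tab$fas_exceeds_mcid),
                          time = sum(tab$time_exceeds_mcid)))
}

#' Summarise the per-object manual-dexterity assessment
#'
#' Aggregates the game-based object-manipulation assessment (success rate
#' in percent and response time in milliseconds, each already the average
#' of leftward and rightward movements) over the three test objects
#' (coffee mug, wine glass, tennis ball): per participant, the mean and
#' sample SD across objects for pre, post and change; at group level, the
#' mean and SD of the per-participant (unrounded) change means. SR change
#' is post minus pre (improvement); response-time change is pre minus
#' post (decrease).
#'
#' @param assessments data.frame in long format with columns
#'   `participant`, `object` (`coffee_mug`, `wine_glass`, `tennis_ball`),
#'   `phase` (`pre`/`post`), `success_rate_pct`, `response_time_ms`.
#' @return list with `per_object` (wide per participant x object table
#'   including changes), `per_participant` (list, per participant, of
#'   [group_summary()] results for the six cells) and `group` (list with
#'   `sr_change`, `rt_change` group summaries over per-participant
#'   means).
#' @export
assessment_table <- function(assessments) {
  need <- c("participant", "object", "phase", "success_rate_pct",
            "response_time_ms")
  if (!all(need %in% names(assessments))) {
    stop_rtp("assessment table must have columns: ",
             paste(need, collapse = ", "))
  }
  objects <- c("coffee_mug", "wine_glass", "tennis_ball")
  parts <- unique(assessments$participant)
  wide <- list()
  per_part <- list()
  sr_change_means <- numeric(0)
  rt_change_means <- numeric(0)
  for (p in parts) {
    sub <- assessments[assessments$participant == p, , drop = FALSE]
    cell <- function(obj, ph, col) {
      v <- sub[sub$object == obj & sub$phase == ph, col]
      if (length(v) != 1L) {
        stop_rtp(sprintf("participant %s is missing %s/%s", p, obj, ph))
      }
      v
    }
    sr_pre <- vapply(objects, cell, numeric(1), ph = "pre",
                     col = "success_rate_pct")
    sr_post <- vapply(objects, cell, numeric(1), ph = "post",
                      col = "success_rate_pct")
    rt_pre <- vapply(objects, cell, numeric(1), ph = "pre",
                     col = "response_time_ms")
    rt_post <- vapply(objects, cell, numeric(1), ph = "post",
                      col = "response_time_ms")
    sr_chg <- sr_post - sr_pre
    rt_chg <- rt_pre - rt_post
    wide[[length(wide) + 1L]] <- data.frame(
      participant = p, object = objects,
      sr_pre = sr_pre, sr_post = sr_post, sr_change = sr_chg,
      rt_pre = rt_pre, rt_post = rt_post, rt_change = rt_chg,
      row.names = NULL)
    per_part[[as.character(p)]] <- list(
      sr_pre = group_summary(sr_pre), sr_post = group_summary(sr_post),
      sr_change = group_summary(sr_chg), rt_pre = group_summary(rt_pre),
      rt_post = group_summary(rt_post), rt_change = group_summary(rt_chg))
    sr_change_means <- c(sr_change_means, mean(sr_chg))
    rt_change_means <- c(rt_change_means, mean(rt_chg))
  }
  list(per_object = do.call(rbind, wide),
       per_participant = per_part,
       group = list(sr_change = group_summary(sr_change_means),
                    rt_change = group_summary(rt_change_means)))
}
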
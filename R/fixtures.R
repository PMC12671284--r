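#' Path to a bundled fixture file
#'
#' The package ships small CSV transcriptions of the published
#' feasibility-study data as versioned fixtures: participant
#' demographics, the pre/post WMFT totals, the per-object manual
#' dexterity assessment scores, the commercial game catalog, and the
#' printed "Average (SD)" summary cells used as a regression reference.
#'
#' @param name fixture file name, one of `"wmft_scores.csv"`,
#'   `"object_assessments.csv"`, `"participants.csv"`,
#'   `"game_catalog.csv"`, `"printed_summaries.csv"`.
#' @return absolute path to the installed fixture.
#' @export
rtp_fixture <- function(name) {
  p <- system.file("extdata", name, package = "rtpgame")
  if (p == "") stop_rtp("missing fixture file: ", name)
  p
}

#' Load the bundled clinical fixtures
#'
#' @return a data.frame (see the individual fixture headers).
#' @rdname fixtures
#' @export
load_wmft_fixture <- function() {
  utils::read.csv(rtp_fixture("wmft_scores.csv"))
}

#' @rdname fixtures
#' @export
load_assessment_fixture <- function() {
  utils::read.csv(rtp_fixture("object_assessments.csv"))
}

#' @rdname fixtures
#' @export
load_participants_fixture <- function() {
  utils::read.csv(rtp_fixture("participants.csv"))
}

#' @rdname fixtures
#' @export
load_game_catalog <- function() {
  utils::read.csv(rtp_fixture("game_catalog.csv"))
}

#' @rdname fixtures
#' @export
load_printed_summaries <- function() {
  utils::read.csv(rtp_fixture("printed_summaries.csv"))
}

round_fn <- function(rounding) {
  switch(rounding,
         half_up = function(x) round_half_up(x, 0L),
         half_even = function(x) round(x, 0L))
}

#' Recompute the published summary tables from the raw fixtures
#'
#' Rebuilds every "Average (SD)" cell of the WMFT outcome table and the
#' per-object assessment table, plus the group-level headline numbers,
#' from the raw per-participant fixture values, and diffs each cell
#' against the transcribed printed summaries. This is the package's
#' regression gate: all cells must match exactly under sample SD (n - 1)
#' and half-away-from-zero integer rounding. `rounding = "half_even"`
#' (banker's rounding, base R `round`) is provided as a sensitivity
#' control; on this particular data no cell sits on a .5 tie, so both
#' roundings agree (asserted by a test).
#'
#' @param rounding `"half_up"` (report convention, default) or
#'   `"half_even"`.
#' @return list with `comparison` (one row per cell: computed and
#'   printed mean/SD and a `match` flag), `ok` (all cells match),
#'   `wmft` (the [wmft_outcome_table()] result), `assessment` (the
#'   [assessment_table()] result) and `mcid_counts`.
#' @export
reproduce_tables <- function(rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  rnd <- round_fn(rounding)
  wm <- wmft_outcome_table(load_wmft_fixture())
  as_tab <- assessment_table(load_assessment_fixture())
  printed <- load_printed_summaries()

  rows <- list()
  add <- function(table, participant, measure, phase, gs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      table = table, participant = as.character(participant),
      measure = measure, phase = phase,
      computed_mean = rnd(gs$mean), computed_sd = rnd(gs$sd))
  }
  map4 <- list(fas_pre = c("fas", "pre"), fas_post = c("fas", "post"),
               fas_change = c("fas", "change"), time_pre = c("time", "pre"),
               time_post = c("time", "post"),
               time_change = c("time", "change"))
  for (nm in names(map4)) {
    add("wmft", "group", map4[[nm]][1L], map4[[nm]][2L], wm$summary[[nm]])
  }
  map5 <- list(sr_pre = c("sr", "pre"), sr_post = c("sr", "post"),
               sr_change = c("sr", "change"), rt_pre = c("rt", "pre"),
               rt_post = c("rt", "post"), rt_change = c("rt", "change"))
  for (p in names(as_tab$per_participant)) {
    for (nm in names(map5)) {
      add("assessment", p, map5[[nm]][1L], map5[[nm]][2L],
          as_tab$per_participant[[p]][[nm]])
    }
  }
  add("headline", "group", "sr", "change", as_tab$group$sr_change)
  add("headline", "group", "rt", "change", as_tab$group$rt_change)
  add("headline", "group", "fas", "change", wm$summary$fas_change)
  add("headline", "group", "time", "change", wm$summary$time_change)

  comp <- do.call(rbind, rows)
  merged <- merge(comp, printed,
                  by = c("table", "participant", "measure", "phase"),
                  all = TRUE, sort = FALSE)
  names(merged)[names(merged) == "mean"] <- "printed_mean"
  names(merged)[names(merged) == "sd"] <- "printed_sd"
  merged$match <- !is.na(merged$computed_mean) &
    !is.na(merged$printed_mean) &
    merged$computed_mean == merged$printed_mean &
    merged$computed_sd == merged$printed_sd
  list(comparison = merged, ok = all(merged$match), wmft = wm,
       assessment = as_tab, mcid_counts = wm$mcid_counts)
}

#' Render the outcome tables as Markdown
#'
#' @param repro result of [reproduce_tables()].
#' @return character vector of Markdown lines (invisibly printed by the
#'   CLI `reproduce-tables` verb).
#' @export
render_tables_markdown <- function(repro = reproduce_tables()) {
  wm <- repro$wmft
  out <- c("## WMFT outcomes (functional ability score, total time)", "",
           "| Participant | FAS pre | FAS post | FAS change | Time pre (s) | Time post (s) | Time change (s) |",
           "|---|---|---|---|---|---|---|")
  tb <- wm$table
  for (i in seq_len(nrow(tb))) {
    out <- c(out, sprintf("| %s | %g | %g | %g | %g | %g | %g |",
                          tb$participant[i], tb$fas_pre[i], tb$fas_post[i],
                          tb$fas_change[i], tb$time_pre_s[i],
                          tb$time_post_s[i], tb$time_change_s[i]))
  }
  s <- wm$summary
  out <- c(out, sprintf("| Average (SD) | %s | %s | %s | %s | %s | %s |",
                        s$fas_pre$cell, s$fas_post$cell, s$fas_change$cell,
                        s$time_pre$cell, s$time_post$cell,
                        s$time_change$cell), "",
           "## Object manipulation assessment (SR %, response time ms)", "",
           "| Participant | SR pre | SR post | SR change | RT pre | RT post | RT change |",
           "|---|---|---|---|---|---|---|")
  for (p in names(repro$assessment$per_participant)) {
    pp <- repro$assessment$per_participant[[p]]
    out <- c(out, sprintf("| %s (avg (SD)) | %s | %s | %s | %s | %s | %s |",
                          p, pp$sr_pre$cell, pp$sr_post$cell,
                          pp$sr_change$cell, pp$rt_pre$cell,
                          pp$rt_post$cell, pp$rt_change$cell))
  }
  g <- repro$assessment$group
  out <- c(out, sprintf("| Group change (SD) | | | %s | | | %s |",
                        g$sr_change$cell, g$rt_change$cell))
  out
}
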
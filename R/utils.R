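#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (2.5 -> 3, -2.5 -> -3), the convention used when rendering report
#' tables. Base R's `round()` rounds half to even and would disagree on
#' ties.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector, rounded.
#' @export
#' @examples
#' round_half_up(c(2.5, -2.5, 2.4)) # 3 -3 2
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_rtp <- function(..., class = "rtp_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lo = -Inf, hi = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lo || x > hi) {
    stop_rtp(sprintf("'%s' must be a single number in [%s, %s], got: %s",
                     name, format(lo), format(hi),
                     paste(format(x), collapse = ", ")),
             class = "rtp_config_error")
  }
  invisible(x)
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_rtp(sprintf("'%s' must be one of: %s", name,
                     paste(choices, collapse = ", ")),
             class = "rtp_config_error")
  }
  invisible(x)
}

# Truncated-at-zero normal draw: resample negatives (mean >= 0 assumed,
# truncation mass is small for the latencies used here).
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < 0
  }
  x
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so session runs do not disturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
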
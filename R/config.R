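#' Study configuration
#'
#' Bundles the temporal conventions every other function depends on: the
#' monitoring window, the UTC offset used to assign detections to local days,
#' and the calendar months making up the high- and low-abundance seasons.
#'
#' Day boundaries are taken in *local* time: a detection at 23:59 local and
#' another at 00:01 local the next day fall on different days regardless of
#' the UTC clock. The default offset of -3 h corresponds to Argentina.
#'
#' @param study_start,study_end `Date` (or coercible) first and last day of
#'   the monitoring window.
#' @param local_utc_offset Hours to add to UTC to obtain local time.
#' @param high_season_months,low_season_months Integer month sets (1-12) that
#'   together must partition the calendar; defaults October-February (high)
#'   and March-September (low).
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config("2019-11-01", "2021-03-12")
#' study_duration_days(cfg)  # 497
#' @export
study_config <- function(study_start, study_end, local_utc_offset = -3,
                         high_season_months = c(10:12, 1:2),
                         low_season_months = 3:9) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end))
    stop("study_start/study_end must be valid dates")
  if (study_end < study_start)
    stop("study_end precedes study_start")
  hs <- as.integer(high_season_months)
  ls <- as.integer(low_season_months)
  if (!setequal(c(hs, ls), 1:12) || length(intersect(hs, ls)) > 0)
    stop("high_season_months and low_season_months must partition 1..12")
  structure(list(
    study_start = study_start,
    study_end = study_end,
    local_utc_offset = as.numeric(local_utc_offset),
    high_season_months = hs,
    low_season_months = ls
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study window:", format(x$study_start), "to", format(x$study_end),
      sprintf("(%d days)\n", study_duration_days(x)))
  cat("Local UTC offset:", x$local_utc_offset, "h\n")
  cat("High season months:", paste(x$high_season_months, collapse = ", "), "\n")
  invisible(x)
}

#' Study duration in whole days
#'
#' Exclusive day difference `study_end - study_start`. This convention (not
#' counting both endpoints) is the one under which a window from 1 November
#' 2019 to 12 March 2021 spans 497 days, the denominator used by the minimum
#' residency index.
#'
#' @param config A [study_config()], or a start date when `end` is given.
#' @param end Optional end date when `config` is a date.
#' @return Integer number of days.
#' @export
study_duration_days <- function(config, end = NULL) {
  if (inherits(config, "study_config")) {
    s <- config$study_start; e <- config$study_end
  } else {
    s <- as.Date(config); e <- as.Date(end)
  }
  if (is.na(s) || is.na(e)) stop("invalid dates")
  if (e < s) stop("end precedes start")
  as.integer(e - s)
}

#' Local-day and local-hour helpers
#'
#' Map UTC instants onto the study's local calendar.
#'
#' @param time `POSIXct` instants (UTC).
#' @param config A [study_config()] (only `local_utc_offset` is used).
#' @return `local_day()` a `Date`; `local_hour()` integer hour 0-23;
#'   `local_hour_frac()` fractional hours in `[0, 24)`.
#' @export
local_day <- function(time, config) {
  as.Date(floor((as.numeric(time) + config$local_utc_offset * 3600) / 86400),
          origin = "1970-01-01")
}

#' @rdname local_day
#' @export
local_hour <- function(time, config) {
  as.integer(floor(local_hour_frac(time, config)))
}

#' @rdname local_day
#' @export
local_hour_frac <- function(time, config) {
  ((as.numeric(time) + config$local_utc_offset * 3600) %% 86400) / 3600
}

#' Season of a date or month
#'
#' @param x Dates or integer months.
#' @param config A [study_config()].
#' @return Factor with levels `"high"`, `"low"`.
#' @export
season_of <- function(x, config) {
  m <- if (inherits(x, "Date")) as.integer(format(x, "%m")) else as.integer(x)
  factor(ifelse(m %in% config$high_season_months, "high", "low"),
         levels = c("high", "low"))
}
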
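#' Remove collision-like detections
#'
#' Receivers cannot log a true code collision, so near-simultaneous
#' detections of *different* tags at the *same* receiver are the standard
#' operational proxy: every member of such a group is removed. Exact
#' duplicate rows (same tag, receiver and timestamp) are reduced to a single
#' copy first. With `window = 0` only that deduplication happens.
#'
#' @param det A [detection_table()], time-sorted.
#' @param window Collision window in seconds; two detections belong to the
#'   same group when their time difference is strictly less than `window`.
#' @return The filtered [detection_table()].
#' @export
remove_collisions <- function(det, window = 1) {
  if (!nrow(det)) return(det)
  dup <- duplicated(det[c("timestamp", "tag_id", "receiver_id")])
  det <- restrict_detections(det, !dup)
  if (window <= 0 || nrow(det) < 2) return(det)
  o <- order(det$receiver_id, det$timestamp)
  t <- as.numeric(det$timestamp)[o]
  rec <- det$receiver_id[o]
  tag <- det$tag_id[o]
  n <- length(t)
  drop <- rep(FALSE, n)
  lag <- 1
  repeat {
    i <- seq_len(n - lag)
    close_pair <- rec[i] == rec[i + lag] & (t[i + lag] - t[i]) < window
    if (!any(close_pair)) break
    hit <- close_pair & tag[i] != tag[i + lag]
    drop[i][hit] <- TRUE
    drop[i + lag][hit] <- TRUE
    lag <- lag + 1
    if (lag >= n) break
  }
  keep <- rep(TRUE, n)
  keep[o] <- !drop
  restrict_detections(det, keep)
}

#' Remove daily singleton detections
#'
#' A single detection of a tag at a receiver within a local day carries a
#' high false-detection risk and is removed; groups of two or more at the
#' same (tag, receiver, day) are kept whole.
#'
#' @param det A [detection_table()].
#' @return The filtered [detection_table()].
#' @export
remove_daily_singletons <- function(det) {
  if (!nrow(det)) return(det)
  cfg <- det_config(det)
  key <- paste(det$tag_id, det$receiver_id, local_day(det$timestamp, cfg))
  cnt <- ave(seq_along(key), key, FUN = length)
  restrict_detections(det, cnt >= 2)
}

#' Drop detections on the tagging days
#'
#' Detections logged on the capture/tagging days reflect post-handling
#' stress rather than natural behaviour and are excluded.
#'
#' @param det A [detection_table()].
#' @param tagging_days `Date` vector of local days to remove (may be empty).
#' @return The filtered [detection_table()].
#' @export
drop_tagging_window <- function(det, tagging_days) {
  if (!nrow(det) || !length(tagging_days)) return(det)
  cfg <- det_config(det)
  keep <- !(local_day(det$timestamp, cfg) %in% as.Date(tagging_days))
  restrict_detections(det, keep)
}

#' Exclude non-representative tags
#'
#' Tags whose entire detection history falls within the first `horizon_days`
#' of the study cannot be distinguished from early tag loss, tagging-induced
#' mortality or immediate permanent emigration, and are excluded. The
#' horizon is measured from `study_start` (day 1), not from each tag's
#' tagging date.
#'
#' @param det A [detection_table()].
#' @param horizon_days Length of the initial horizon (default 5 days).
#' @return List with elements `detections` (filtered table) and `excluded`
#'   (`data.frame` of `tag_id`, `reason`).
#' @export
exclude_nonrepresentative_tags <- function(det, horizon_days = 5) {
  cfg <- det_config(det)
  if (!nrow(det))
    return(list(detections = det,
                excluded = data.frame(tag_id = character(), reason = character())))
  day <- local_day(det$timestamp, cfg)
  last <- tapply(day, det$tag_id, max)
  cutoff <- cfg$study_start + horizon_days - 1   # days 1..horizon_days
  bad <- names(last)[as.Date(last, origin = "1970-01-01") <= cutoff]
  excluded <- data.frame(
    tag_id = bad,
    reason = rep(sprintf("all detections within first %d days of the study",
                         horizon_days), length(bad)),
    stringsAsFactors = FALSE)
  list(detections = restrict_detections(det, !(det$tag_id %in% bad)),
       excluded = excluded)
}

#' Flag stationary tags
#'
#' A tag detected day after day at a single receiver for a long stretch is
#' more plausibly a shed or expelled transmitter lying on the bottom than a
#' resident animal. This is a report-and-inspect step: flagged tags are
#' returned, not silently removed.
#'
#' @param det A [detection_table()].
#' @param min_span_days Minimum span (first to last day of the run,
#'   inclusive) to flag; default 30.
#' @param max_gap_days Maximum tolerated gap in detected days within the run
#'   (default 1).
#' @return Character vector of flagged tag ids.
#' @export
flag_stationary_tags <- function(det, min_span_days = 30, max_gap_days = 1) {
  if (!nrow(det)) return(character())
  cfg <- det_config(det)
  day <- local_day(det$timestamp, cfg)
  flagged <- character()
  for (tg in unique(det$tag_id)) {
    sel <- det$tag_id == tg
    dd <- sort(unique(day[sel]))
    if (length(dd) < 2) next
    gap <- as.integer(diff(dd))
    run_id <- cumsum(c(0, gap > max_gap_days + 1))
    for (r in unique(run_id)) {
      rd <- dd[run_id == r]
      span <- as.integer(rd[length(rd)] - rd[1]) + 1
      if (span < min_span_days) next
      recs <- unique(det$receiver_id[sel & day %in% rd])
      if (length(recs) == 1) { flagged <- c(flagged, tg); break }
    }
  }
  flagged
}

#' Run the full curation chain
#'
#' Applies, in this fixed order: collision removal, daily-singleton removal,
#' tagging-window removal, non-representative-tag exclusion, and stationary
#' tag flagging (optionally excluding flagged tags). The order matters:
#' removing collisions can create new daily singletons, so singleton removal
#' must come after it.
#'
#' @param det A [detection_table()].
#' @param collision_window Seconds, see [remove_collisions()].
#' @param tagging_days `Date` vector, see [drop_tagging_window()].
#' @param horizon_days See [exclude_nonrepresentative_tags()].
#' @param stationary_min_span See [flag_stationary_tags()].
#' @param exclude_stationary Remove flagged stationary tags (default FALSE:
#'   flag only, exclusion is an inspection decision).
#' @return List with `detections` (curated table) and `report`
#'   (a `curation_report`).
#' @export
curate_detections <- function(det, collision_window = 1,
                              tagging_days = NULL, horizon_days = 5,
                              stationary_min_span = 30,
                              exclude_stationary = FALSE) {
  n_input <- nrow(det)
  d1 <- remove_collisions(det, collision_window)
  d2 <- remove_daily_singletons(d1)
  d3 <- drop_tagging_window(d2, tagging_days)
  ex <- exclude_nonrepresentative_tags(d3, horizon_days)
  d4 <- ex$detections
  stationary <- flag_stationary_tags(d4, stationary_min_span)
  if (exclude_stationary && length(stationary))
    d4 <- restrict_detections(d4, !(d4$tag_id %in% stationary))
  report <- structure(list(
    n_input = n_input,
    n_collision_removed = n_input - nrow(d1),
    n_singleton_removed = nrow(d1) - nrow(d2),
    n_tagging_window_removed = nrow(d2) - nrow(d3),
    n_nonrepresentative_removed = nrow(d3) - nrow(ex$detections),
    n_stationary_removed = nrow(ex$detections) - nrow(d4),
    n_output = nrow(d4),
    excluded_tags = ex$excluded,
    stationary_tags = stationary
  ), class = "curation_report")
  list(detections = d4, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Detection curation report\n")
  cat("  input detections:        ", x$n_input, "\n")
  cat("  collision-like removed:  ", x$n_collision_removed, "\n")
  cat("  daily singletons removed:", x$n_singleton_removed, "\n")
  cat("  tagging-window removed:  ", x$n_tagging_window_removed, "\n")
  cat("  non-representative tags: ", nrow(x$excluded_tags),
      sprintf("(%d detections)\n", x$n_nonrepresentative_removed))
  cat("  stationary tags flagged: ", length(x$stationary_tags),
      sprintf("(%d detections removed)\n", x$n_stationary_removed))
  cat("  output detections:       ", x$n_output, "\n")
  invisible(x)
}
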
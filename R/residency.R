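#' Build the daily presence matrix
#'
#' Collapses curated detections into a tags-by-days boolean presence matrix
#' (a tag is "present" on a local day when it has at least one detection),
#' together with the set of receivers each tag visited on each day. This is
#' the source object for every residency, roaming and abundance statistic.
#'
#' @param det A curated [detection_table()].
#' @param tags Optional character vector fixing the tag set (rows); defaults
#'   to the tags seen in `det`.
#' @param receivers Optional character vector fixing the receiver set;
#'   defaults to the receivers seen in `det`.
#' @return A `presence_matrix`: list with `presence` (logical tags x days),
#'   `n_receivers` (integer tags x days), `by_receiver` (logical array
#'   tags x days x receivers), `days`, `tags`, `receivers`, `config`.
#' @export
build_presence <- function(det, tags = NULL, receivers = NULL) {
  cfg <- det_config(det)
  days <- seq(cfg$study_start, cfg$study_end, by = "day")
  if (is.null(tags)) tags <- sort(unique(det$tag_id))
  if (is.null(receivers)) receivers <- sort(unique(det$receiver_id))
  nt <- length(tags); nd <- length(days); nr <- length(receivers)
  by_receiver <- array(FALSE, dim = c(nt, nd, nr),
                       dimnames = list(tags, format(days), receivers))
  if (nrow(det)) {
    d <- local_day(det$timestamp, cfg)
    it <- match(det$tag_id, tags)
    id <- match(d, days)
    ir <- match(det$receiver_id, receivers)
    ok <- !is.na(it) & !is.na(id) & !is.na(ir)
    idx <- unique(cbind(it[ok], id[ok], ir[ok]))
    by_receiver[idx] <- TRUE
  }
  n_receivers <- apply(by_receiver, c(1, 2), sum)
  structure(list(
    presence = n_receivers > 0,
    n_receivers = n_receivers,
    by_receiver = by_receiver,
    days = days, tags = tags, receivers = receivers, config = cfg
  ), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Daily presence matrix: %d tags x %d days, %d receivers\n",
              length(x$tags), length(x$days), length(x$receivers)))
  cat(sprintf("  tag-days present: %d (%.1f%%)\n", sum(x$presence),
              100 * mean(x$presence)))
  invisible(x)
}

#' Minimum and maximum residency indices
#'
#' For each tag with at least one detected day: the *maximum* residency
#' index divides days detected by the inclusive span from first to last
#' detection (it ignores possible absence after the last detection, hence an
#' upper bracket); the *minimum* residency index divides days detected by
#' the full study duration (a lower bracket that charges the tag for every
#' undetected study day). The duration is the exclusive day difference of
#' the window while day spans count both endpoints, so for a tag whose span
#' covers the whole window the minimum is capped at the maximum; the two
#' indices are then equal exactly when the detection span covers the study
#' window. Each tag is also categorized from its minimum residency via
#' [categorize_residency()].
#'
#' @param p A [build_presence()] object.
#' @return `data.frame` with one row per detected tag: `tag_id`,
#'   `first_day`, `last_day`, `days_detected`, `min_residency`,
#'   `max_residency`, `category`.
#' @export
residency_indices <- function(p) {
  dur <- study_duration_days(p$config)
  rows <- lapply(seq_along(p$tags), function(i) {
    v <- p$presence[i, ]
    if (!any(v)) return(NULL)
    f <- which(v)[1]; l <- which(v)[length(which(v))]
    dd <- sum(v)
    mx <- dd / (l - f + 1)
    data.frame(tag_id = p$tags[i],
               first_day = p$days[f], last_day = p$days[l],
               days_detected = dd,
               min_residency = min(dd / dur, mx),
               max_residency = mx,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tag_id = character(), first_day = as.Date(character()),
                      last_day = as.Date(character()), days_detected = integer(),
                      min_residency = numeric(), max_residency = numeric(),
                      category = categorize_residency(numeric())))
  out$category <- categorize_residency(out$min_residency)
  rownames(out) <- NULL
  out
}

#' Roaming index
#'
#' The average, over the days a tag was present, of the fraction of array
#' receivers it visited that day. With `R` receivers the index ranges from
#' `1/R` (one receiver per present day) to 1 (all receivers every present
#' day).
#'
#' @param p A [build_presence()] object.
#' @param R Number of active receivers; defaults to the number of receivers
#'   in `p`.
#' @param period Optional `Date` vector restricting the days considered
#'   (e.g. one season).
#' @return Named numeric vector, one value per tag (`NA` for tags never
#'   present in the period).
#' @export
roaming_index <- function(p, R = NULL, period = NULL) {
  if (is.null(R)) R <- length(p$receivers)
  stopifnot(R >= 1)
  cols <- if (is.null(period)) seq_along(p$days) else
    which(p$days %in% as.Date(period))
  vapply(seq_along(p$tags), function(i) {
    pres <- p$presence[i, cols]
    if (!any(pres)) return(NA_real_)
    mean(p$n_receivers[i, cols][pres] / R)
  }, numeric(1)) |> stats::setNames(p$tags)
}

#' Residency categories
#'
#' Thresholds on the minimum residency index: below 0.1 a *vagrant*, 0.1 to
#' 0.5 (inclusive) a *short-term* resident, above 0.5 a *long-term*
#' resident.
#'
#' @param min_res Numeric minimum residency values in `[0, 1]`.
#' @return Factor with levels `vagrant`, `short-term`, `long-term`.
#' @export
categorize_residency <- function(min_res) {
  lv <- c("vagrant", "short-term", "long-term")
  factor(ifelse(min_res < 0.1, lv[1], ifelse(min_res <= 0.5, lv[2], lv[3])),
         levels = lv)
}

#' Presence and absence bouts
#'
#' Run-length encodes each tag's daily presence vector restricted to its
#' first-to-last detection span. Presence bouts are stretches of consecutive
#' detected days; absence bouts are the undetected gaps *between*
#' detections (time after the final detection is never an absence bout).
#'
#' @param p A [build_presence()] object.
#' @return `data.frame` with `tag_id`, `type` (`presence`/`absence`),
#'   `length` (days), in chronological order within tag.
#' @export
bouts <- function(p) {
  rows <- lapply(seq_along(p$tags), function(i) {
    v <- p$presence[i, ]
    if (!any(v)) return(NULL)
    w <- which(v)
    span <- v[w[1]:w[length(w)]]
    r <- rle(span)
    data.frame(tag_id = p$tags[i],
               type = ifelse(r$values, "presence", "absence"),
               length = r$lengths, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tag_id = character(), type = character(),
                      length = integer())
  rownames(out) <- NULL
  out
}

# Last detected day index per tag (NA when never detected).
last_detected_index <- function(p) {
  vapply(seq_along(p$tags), function(i) {
    w <- which(p$presence[i, ])
    if (length(w)) w[length(w)] else NA_integer_
  }, integer(1))
}

#' Daily proportion of detected over remaining individuals
#'
#' A departure-corrected abundance index: for each study day, the number of
#' tags detected divided by the number of tags that have not yet permanently
#' left the array. A tag leaves the denominator the day *after* its final
#' detection. When no tag remains the proportion is `NA`, not 0.
#'
#' @param p A [build_presence()] object.
#' @param sex Optional: restrict to tags of one sex (`"female"`/`"male"`);
#'   requires `tags_meta`.
#' @param tags_meta Optional tag metadata `data.frame` (`tag_id`, `sex`).
#' @return `data.frame` with `day`, `n_detected`, `n_remaining`,
#'   `proportion`.
#' @export
remaining_proportion <- function(p, sex = NULL, tags_meta = NULL) {
  keep <- rep(TRUE, length(p$tags))
  if (!is.null(sex)) {
    if (is.null(tags_meta)) stop("sex filtering requires tags_meta")
    sx <- tags_meta$sex[match(p$tags, tags_meta$tag_id)]
    keep <- !is.na(sx) & sx == sex
  }
  last <- last_detected_index(p)
  idx <- which(keep & !is.na(last))
  nd <- length(p$days)
  n_detected <- if (length(idx)) colSums(p$presence[idx, , drop = FALSE]) else
    rep(0L, nd)
  n_remaining <- vapply(seq_len(nd), function(d)
    sum(last[idx] >= d), integer(1))
  data.frame(day = p$days,
             n_detected = as.integer(n_detected),
             n_remaining = n_remaining,
             proportion = ifelse(n_remaining > 0,
                                 n_detected / n_remaining, NA_real_))
}

#' Monthly mean detected/remaining proportion per receiver
#'
#' For each receiver and calendar month: the mean over days of (tags
#' detected at that receiver that day) / (tags remaining that day). This is
#' the seasonal occupancy profile of the array, receiver by receiver.
#'
#' @param p A [build_presence()] object.
#' @return `data.frame` with `month` (1-12), `receiver_id`,
#'   `mean_proportion`.
#' @export
monthly_receiver_profile <- function(p) {
  rp <- remaining_proportion(p)
  month <- as.integer(format(p$days, "%m"))
  rows <- list()
  for (r in seq_along(p$receivers)) {
    det_r <- colSums(matrix(p$by_receiver[, , r], nrow = length(p$tags)))
    prop <- ifelse(rp$n_remaining > 0, det_r / rp$n_remaining, NA_real_)
    agg <- tapply(prop, month, mean, na.rm = TRUE)
    rows[[r]] <- data.frame(month = as.integer(names(agg)),
                            receiver_id = p$receivers[r],
                            mean_proportion = ifelse(is.nan(as.numeric(agg)),
                                                     0, as.numeric(agg)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$receiver_id, out$month), ]
}
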
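#' Construct a detection table
#'
#' The backbone object of the pipeline: one row per logged transmission, with
#' a UTC timestamp, the transmitting tag and the logging receiver. Rows are
#' kept time-sorted. Most users will obtain one from [read_detections()] or
#' [simulate_telemetry()] rather than calling this directly.
#'
#' @param timestamp `POSIXct` (UTC) detection instants.
#' @param tag_id,receiver_id Character identifiers.
#' @param config A [study_config()] attached as an attribute.
#' @return A `detection_table` (a `data.frame`).
#' @export
detection_table <- function(timestamp, tag_id, receiver_id, config) {
  stopifnot(inherits(config, "study_config"))
  if (!inherits(timestamp, "POSIXct"))
    stop("timestamp must be POSIXct")
  d <- data.frame(timestamp = timestamp,
                  tag_id = as.character(tag_id),
                  receiver_id = as.character(receiver_id),
                  stringsAsFactors = FALSE)
  d <- d[order(d$timestamp, d$tag_id, d$receiver_id), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "config") <- config
  class(d) <- c("detection_table", "data.frame")
  d
}

det_config <- function(det) {
  cfg <- attr(det, "config")
  if (is.null(cfg)) stop("detection table carries no study_config")
  cfg
}

# Subsetting keeps class and config.
restrict_detections <- function(det, keep) {
  cfg <- det_config(det)
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("detection_table", "data.frame")
  out
}

parse_utc <- function(x, what = "timestamp") {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  t <- rep(as.POSIXct(NA), length(x))
  for (fmt in formats) {
    idx <- which(is.na(t))
    if (!length(idx)) break
    t[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"), tz = "UTC")
  }
  bad <- which(is.na(t) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop(sprintf("unparseable %s at row(s) %s (first value: '%s')",
                 what, paste(utils::head(bad, 5), collapse = ", "), x[bad[1]]))
  attr(t, "tzone") <- "UTC"
  t
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

#' Read raw detections from a receiver-export style file
#'
#' Reads comma- or tab-delimited text with a header naming the timestamp, tag
#' and receiver columns (ISO-8601 timestamps, assumed UTC). Rows whose local
#' day falls outside the study window are dropped and the count reported via
#' `message()`. Deduplication is deliberately *not* performed here: identical
#' rows are retained and handled by the curation step.
#'
#' @param path Path to the delimited file.
#' @param config A [study_config()].
#' @param col_map Named character vector mapping the canonical names
#'   `timestamp`, `tag_id`, `receiver_id` to the file's column names; adapt
#'   vendor exports here.
#' @param receivers,tags Optional metadata tables (from [read_receivers()] /
#'   [read_tags()]) used to validate identifiers.
#' @param unknown What to do with rows referencing unknown receivers or tags
#'   when metadata are supplied: `"error"` (default) or `"drop"`.
#' @return A [detection_table()].
#' @export
read_detections <- function(path, config,
                            col_map = c(timestamp = "timestamp",
                                        tag_id = "tag_id",
                                        receiver_id = "receiver_id"),
                            receivers = NULL, tags = NULL,
                            unknown = c("error", "drop")) {
  unknown <- match.arg(unknown)
  raw <- read_delim_auto(path)
  need <- col_map[c("timestamp", "tag_id", "receiver_id")]
  miss <- need[!need %in% names(raw)]
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  ts <- parse_utc(as.character(raw[[need[["timestamp"]]]]))
  tag <- as.character(raw[[need[["tag_id"]]]])
  rec <- as.character(raw[[need[["receiver_id"]]]])

  if (!is.null(receivers) || !is.null(tags)) {
    bad <- rep(FALSE, length(ts))
    if (!is.null(receivers)) bad <- bad | !(rec %in% receivers$receiver_id)
    if (!is.null(tags)) bad <- bad | !(tag %in% tags$tag_id)
    if (any(bad)) {
      if (unknown == "error")
        stop(sprintf("%d detection(s) reference unknown receivers/tags (first row %d)",
                     sum(bad), which(bad)[1]))
      message(sum(bad), " detection(s) with unknown receiver/tag dropped")
      ts <- ts[!bad]; tag <- tag[!bad]; rec <- rec[!bad]
    }
  }

  day <- local_day(ts, config)
  inside <- day >= config$study_start & day <= config$study_end
  if (any(!inside))
    message(sum(!inside), " detection(s) outside the study window dropped")
  detection_table(ts[inside], tag[inside], rec[inside], config)
}

#' Write a detection table back to CSV
#'
#' Timestamps are written as ISO-8601 with microsecond precision so that a
#' write/read round trip reproduces the table.
#'
#' @param det A [detection_table()].
#' @param path Output path.
#' @export
write_detections <- function(det, path) {
  out <- data.frame(
    timestamp = format(det$timestamp, "%Y-%m-%d %H:%M:%OS6", tz = "UTC"),
    tag_id = det$tag_id, receiver_id = det$receiver_id)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read receiver deployment metadata
#'
#' Expects columns `receiver_id`, `x`, `y` (planar coordinates in metres),
#' `deploy_date`, `recover_date` and optionally `status` (`active`/`lost`).
#'
#' @param path Path to a delimited file.
#' @param water Optional water polygon; when given, receiver positions are
#'   checked to fall in water.
#' @return A `data.frame` of receivers.
#' @export
read_receivers <- function(path, water = NULL) {
  r <- read_delim_auto(path)
  need <- c("receiver_id", "x", "y", "deploy_date", "recover_date")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("receivers file lacks column(s): ",
                         paste(miss, collapse = ", "))
  r$receiver_id <- as.character(r$receiver_id)
  r$deploy_date <- as.Date(r$deploy_date)
  r$recover_date <- as.Date(r$recover_date)
  if (is.null(r$status)) r$status <- "active"
  if (any(r$deploy_date >= r$recover_date))
    stop("deploy_date must precede recover_date for every receiver")
  if (!is.null(water)) {
    inw <- point_in_polygon(r$x, r$y, water)
    if (any(!inw))
      stop("receiver(s) outside the water polygon: ",
           paste(r$receiver_id[!inw], collapse = ", "))
  }
  r
}

#' Read tag deployment metadata
#'
#' Expects columns `tag_id`, `sex` (`female`/`male`), `total_length` (cm),
#' `tagging_date`, and optionally `emission_min`/`emission_max` (seconds).
#'
#' @param path Path to a delimited file.
#' @return A `data.frame` of tag deployments.
#' @export
read_tags <- function(path) {
  tg <- read_delim_auto(path)
  need <- c("tag_id", "sex", "total_length", "tagging_date")
  miss <- setdiff(need, names(tg))
  if (length(miss)) stop("tags file lacks column(s): ",
                         paste(miss, collapse = ", "))
  tg$tag_id <- as.character(tg$tag_id)
  tg$sex <- as.character(tg$sex)
  if (!all(tg$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  tg$tagging_date <- as.Date(tg$tagging_date)
  if (any(tg$total_length <= 100 | tg$total_length >= 300))
    stop("total_length outside the plausible adult range (100, 300) cm")
  if (is.null(tg$emission_min)) tg$emission_min <- 60
  if (is.null(tg$emission_max)) tg$emission_max <- 180
  if (any(tg$emission_min >= tg$emission_max))
    stop("emission interval must satisfy min < max")
  tg
}

#' Read tide extremes (high/low water table)
#'
#' Expects columns `time`, `height` (m) and `kind` (`high`/`low`). The kinds
#' must alternate in time order; a violation is reported with the offending
#' pair of rows.
#'
#' @param path Path to a delimited file.
#' @return A `data.frame` of class `tide_extremes`, time-sorted.
#' @export
read_tide_extremes <- function(path) {
  x <- read_delim_auto(path)
  miss <- setdiff(c("time", "height", "kind"), names(x))
  if (length(miss)) stop("tide file lacks column(s): ",
                         paste(miss, collapse = ", "))
  tide_extremes(parse_utc(as.character(x$time), "tide time"),
                as.numeric(x$height), as.character(x$kind))
}

#' @rdname read_tide_extremes
#' @param time,height,kind Vectors building the table directly.
#' @export
tide_extremes <- function(time, height, kind) {
  if (!all(kind %in% c("high", "low"))) stop("kind must be 'high' or 'low'")
  if (!length(time)) stop("empty tide extreme series")
  o <- order(time)
  x <- data.frame(time = time[o], height = height[o], kind = kind[o],
                  stringsAsFactors = FALSE)
  if (nrow(x) > 1) {
    same <- which(x$kind[-1] == x$kind[-nrow(x)])
    if (length(same))
      stop(sprintf("tide extremes do not alternate: rows %d and %d are both '%s'",
                   same[1], same[1] + 1, x$kind[same[1]]))
  }
  class(x) <- c("tide_extremes", "data.frame")
  x
}

#' Read a daily sea-surface temperature series
#'
#' Expects columns `date` and `sst_c` (degrees Celsius).
#'
#' @param path Path to a delimited file.
#' @return A `data.frame` with `date` (`Date`) and `sst_c`.
#' @export
read_sst <- function(path) {
  x <- read_delim_auto(path)
  miss <- setdiff(c("date", "sst_c"), names(x))
  if (length(miss)) stop("sst file lacks column(s): ",
                         paste(miss, collapse = ", "))
  x$date <- as.Date(x$date)
  x$sst_c <- as.numeric(x$sst_c)
  if (any(is.na(x$date))) stop("unparseable date in sst file")
  x[order(x$date), c("date", "sst_c")]
}

#' Read the water polygon
#'
#' Accepts GeoJSON (`Polygon` or `MultiPolygon`; the first outer ring is
#' used) or a plain delimited file with `x`,`y` vertex columns in metres.
#' The ring is validated to be simple (non-self-intersecting).
#'
#' @param path Path to a `.geojson`/`.json` or delimited vertex file.
#' @return A two-column matrix (`x`, `y`) of class `water_polygon`, open ring
#'   (last vertex not repeated).
#' @export
read_water_polygon <- function(path) {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    geom <- g
    if (identical(g$type, "FeatureCollection")) geom <- g$features[[1]]$geometry
    if (identical(geom$type, "Feature")) geom <- geom$geometry
    ring_list <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported GeoJSON geometry: ", geom$type))
    ring <- do.call(rbind, lapply(ring_list, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  } else {
    v <- read_delim_auto(path)
    miss <- setdiff(c("x", "y"), names(v))
    if (length(miss)) stop("polygon vertex file lacks x/y columns")
    ring <- cbind(v$x, v$y)
  }
  water_polygon(ring)
}

#' @rdname read_water_polygon
#' @param ring Two-column matrix of vertices.
#' @export
water_polygon <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop("polygon ring must have two columns")
  storage.mode(ring) <- "double"
  # drop repeated closing vertex
  n <- nrow(ring)
  if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop("polygon needs at least 3 distinct vertices")
  if (polygon_self_intersects(ring))
    stop("polygon ring is self-intersecting")
  colnames(ring) <- c("x", "y")
  class(ring) <- c("water_polygon", "matrix", "array")
  ring
}

#' Polygon area (shoelace formula)
#'
#' @param poly A [water_polygon()] or two-column vertex matrix.
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x); j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
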
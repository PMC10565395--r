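#' Hourly tide heights from high/low extremes
#'
#' Interpolates the alternating high/low water table with half-cosine arcs,
#' the standard approximation for a mixed semidiurnal regime: between
#' consecutive extremes (h1 at t1, h2 at t2),
#' `h(t) = h1 + (h2 - h1) * (1 - cos(pi * (t - t1)/(t2 - t1))) / 2`,
#' sampled on the hour.
#'
#' @param extremes A [tide_extremes()] table.
#' @param from,to Optional `POSIXct` bounds for the hourly grid; defaults to
#'   the extremes' span.
#' @param max_gap_hours Error if two consecutive extremes are further apart
#'   than this (default 15 h, i.e. a missing extreme).
#' @return `data.frame` with `time` (on-the-hour `POSIXct`, UTC) and
#'   `height` (m).
#' @export
interpolate_hourly <- function(extremes, from = NULL, to = NULL,
                               max_gap_hours = 15) {
  te <- as.numeric(extremes$time)
  he <- extremes$height
  if (length(te) < 2) stop("need at least two tide extremes")
  gaps <- diff(te) / 3600
  if (any(gaps > max_gap_hours))
    stop(sprintf("gap of %.1f h between extremes %d and %d exceeds %g h",
                 max(gaps), which.max(gaps), which.max(gaps) + 1,
                 max_gap_hours))
  t0 <- if (is.null(from)) te[1] else as.numeric(from)
  t1 <- if (is.null(to)) te[length(te)] else as.numeric(to)
  hours <- seq(ceiling(t0 / 3600) * 3600, floor(t1 / 3600) * 3600, by = 3600)
  hours <- hours[hours >= te[1] & hours <= te[length(te)]]
  i <- findInterval(hours, te, rightmost.closed = TRUE)
  i[i >= length(te)] <- length(te) - 1
  frac <- (hours - te[i]) / (te[i + 1] - te[i])
  h <- he[i] + (he[i + 1] - he[i]) * (1 - cos(pi * frac)) / 2
  data.frame(time = as.POSIXct(hours, origin = "1970-01-01", tz = "UTC"),
             height = h)
}

#' Daily tide amplitude
#'
#' Per local day, the highest high water minus the lowest low water among
#' that day's extremes. Days without both a high and a low are `NA`.
#'
#' @param extremes A [tide_extremes()] table.
#' @param config A [study_config()] (for the local-day convention).
#' @return `data.frame` with `day` (`Date`) and `amplitude` (m).
#' @export
daily_amplitude <- function(extremes, config) {
  day <- local_day(extremes$time, config)
  days <- seq(min(day), max(day), by = "day")
  amp <- vapply(days, function(d) {
    sel <- day == d
    hi <- extremes$height[sel & extremes$kind == "high"]
    lo <- extremes$height[sel & extremes$kind == "low"]
    if (!length(hi) || !length(lo)) return(NA_real_)
    max(hi) - min(lo)
  }, numeric(1))
  data.frame(day = days, amplitude = amp)
}

#' Tide height class
#'
#' Classifies hourly heights against the empirical 0.25 and 0.75 quantiles
#' of the full series (linear-interpolation type-7 estimator, the R
#' default): at or below the lower quantile `low`, at or above the upper
#' quantile `high`, otherwise `intermediate`. Degenerate series where the
#' two quantiles coincide fall back to strict comparisons, so a constant
#' series is entirely `intermediate`.
#'
#' @param height Numeric hourly heights.
#' @param probs Quantile pair (default `c(0.25, 0.75)`).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
classify_height <- function(height, probs = c(0.25, 0.75)) {
  q <- stats::quantile(height, probs, names = FALSE, type = 7, na.rm = TRUE)
  lv <- c("low", "intermediate", "high")
  cls <- if (q[1] < q[2]) {
    ifelse(height <= q[1], lv[1], ifelse(height >= q[2], lv[3], lv[2]))
  } else {
    ifelse(height < q[1], lv[1], ifelse(height > q[2], lv[3], lv[2]))
  }
  factor(cls, levels = lv)
}

#' Tide direction
#'
#' `inflow` while the tide rises hour over hour, `outflow` while it falls.
#' An exact zero difference (slack sampled on the hour) inherits the
#' previous hour's label; the first hour takes the label of its leading
#' limb.
#'
#' @param height Numeric hourly heights (chronological).
#' @return Factor with levels `inflow`, `outflow`.
#' @export
classify_direction <- function(height) {
  n <- length(height)
  if (n < 2) stop("need at least two hourly heights")
  d <- c(height[2] - height[1], diff(height))
  lab <- ifelse(d > 0, "inflow", ifelse(d < 0, "outflow", NA))
  # zero differences inherit the previous label; leading zeros look forward
  for (i in seq_len(n)) if (is.na(lab[i]) && i > 1) lab[i] <- lab[i - 1]
  if (anyNA(lab)) {
    first_ok <- which(!is.na(lab))[1]
    if (is.na(first_ok)) stop("tide series is constant; direction undefined")
    lab[seq_len(first_ok - 1)] <- lab[first_ok]
  }
  factor(lab, levels = c("inflow", "outflow"))
}

#' Tide strength
#'
#' `weak` around slack water: an hour is weak when it lies within one hour
#' of a direction reversal (a high or low water) *and* its height differs
#' from that extreme's height by less than `threshold` metres (strict);
#' `strong` otherwise (mid-limb hours, or near-slack hours on a large
#' tide where the height already moved more than the threshold).
#'
#' @param time `POSIXct` hourly instants.
#' @param height Matching hourly heights.
#' @param extremes The [tide_extremes()] table the series derives from.
#' @param threshold Height-change threshold in metres (default 0.5).
#' @return Factor with levels `weak`, `strong`.
#' @export
classify_strength <- function(time, height, extremes, threshold = 0.5) {
  tt <- as.numeric(time)
  te <- as.numeric(extremes$time)
  nearest <- vapply(tt, function(t) which.min(abs(te - t)), integer(1))
  near_slack <- abs(tt - te[nearest]) < 3600
  small_move <- abs(height - extremes$height[nearest]) < threshold
  factor(ifelse(near_slack & small_move, "weak", "strong"),
         levels = c("weak", "strong"))
}

#' Full hourly tide covariate table
#'
#' Convenience wrapper: interpolates hourly heights and attaches the three
#' categorical covariates (height class, direction, strength).
#'
#' @inheritParams interpolate_hourly
#' @inheritParams classify_strength
#' @param probs Quantile pair for [classify_height()].
#' @return `data.frame` with `time`, `height`, `height_class`, `direction`,
#'   `strength`.
#' @export
tide_covariates <- function(extremes, from = NULL, to = NULL,
                            threshold = 0.5, probs = c(0.25, 0.75)) {
  h <- interpolate_hourly(extremes, from, to)
  h$height_class <- classify_height(h$height, probs)
  h$direction <- classify_direction(h$height)
  h$strength <- classify_strength(h$time, h$height, extremes, threshold)
  h
}

#' Calibrate predicted tides against an in-situ logger
#'
#' Fits `logger ~ offset + scale * predicted(t - lag)` by least squares,
#' searching `lag` over a +/-120 min grid (5-min step by default) and
#' keeping the lag with the smallest RMSE (ties resolved toward the
#' smallest absolute lag).
#'
#' @param predicted `data.frame` with `time`, `height` (the astronomic
#'   prediction, e.g. from [interpolate_hourly()]).
#' @param logger `data.frame` with `time`, `height` measured in situ.
#' @param lag_grid Candidate lags in minutes.
#' @return A `tide_calibration`: list with `offset`, `scale`, `lag`
#'   (minutes), `rmse` (m).
#' @export
calibrate_tide <- function(predicted, logger,
                           lag_grid = seq(-120, 120, by = 5)) {
  lag_grid <- lag_grid[order(abs(lag_grid))]
  tp <- as.numeric(predicted$time); hp <- predicted$height
  tl <- as.numeric(logger$time); hl <- logger$height
  best <- NULL
  for (L in lag_grid) {
    ph <- stats::approx(tp, hp, xout = tl - L * 60, rule = 1)$y
    ok <- !is.na(ph)
    if (sum(ok) < 3) next
    fit <- stats::lm.fit(cbind(1, ph[ok]), hl[ok])
    rmse <- sqrt(mean(fit$residuals^2))
    if (is.null(best) || rmse < best$rmse - 1e-12)
      best <- list(offset = unname(fit$coefficients[1]),
                   scale = unname(fit$coefficients[2]),
                   lag = L, rmse = rmse)
  }
  if (is.null(best)) stop("no overlap between predicted and logger series")
  if (best$scale <= 0) warning("calibration scale is not positive")
  structure(best, class = "tide_calibration")
}

#' @export
print.tide_calibration <- function(x, ...) {
  cat(sprintf(
    "Tide calibration: height ~ %.3f + %.3f * predicted(t - %d min), RMSE %.3f m\n",
    x$offset, x$scale, x$lag, x$rmse))
  invisible(x)
}

#' Apply a tide calibration to a predicted series
#'
#' @param cal A [calibrate_tide()] result.
#' @param predicted `data.frame` with `time`, `height`.
#' @return The corrected series (`time`, `height`), on `predicted`'s grid.
#' @export
apply_tide_calibration <- function(cal, predicted) {
  tp <- as.numeric(predicted$time)
  ph <- stats::approx(tp, predicted$height, xout = tp - cal$lag * 60,
                      rule = 2)$y
  data.frame(time = predicted$time, height = cal$offset + cal$scale * ph)
}
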
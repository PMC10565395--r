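#' Define a synthetic tidal-inlet telemetry scenario
#'
#' Describes a narrow tidal inlet monitored by a gate array of receivers,
#' a tagged population with seasonal occupancy and sex-specific departure,
#' within-inlet Ornstein-Uhlenbeck movement with an optional tide-driven
#' drift for males, logistic distance-dependent detection with
#' tide-modulated effective range, and the environmental series (semidiurnal
#' tide with spring-neap modulation, seasonal SST). All defaults are the
#' study conditions the package's tests and recovery experiments assume.
#'
#' @param study_start First monitoring day.
#' @param study_days Study duration in days (exclusive difference), default
#'   497.
#' @param inlet_length,inlet_width Inlet dimensions (m); the water polygon
#'   is the rectangle `[0, inlet_length] x [0, inlet_width]`.
#' @param receiver_x Along-axis receiver positions (m); default five gates
#'   2 km apart along the upper half.
#' @param n_females,n_males Tagged animals per sex.
#' @param q_peak_month Month of peak occupancy (default 12, December).
#' @param q_max,q_min Seasonal daily occupancy probability at peak and
#'   trough.
#' @param sex_differences Master switch: when `FALSE` males follow the
#'   female departure model and have no tide drift (a null scenario).
#' @param male_departure_window Day range (from study start) within which
#'   males depart abruptly.
#' @param female_daily_hazard,female_hazard_start Gradual female departure:
#'   daily departure probability applying from `female_hazard_start` days.
#' @param ou_center,ou_sd_x,ou_sd_y,ou_tau Movement: OU stationary mean
#'   (along-axis, m), stationary s.d. along/across (m), relaxation time (s).
#' @param male_tide_drift Tide response of males (m): the male OU mean sits
#'   `male_tide_drift * (1 - h/max_amplitude)` below `ou_center`, i.e. males
#'   ride the flood up to the common centre and drop toward the lower inlet
#'   (out of the gate array's reach) on the ebb (0 disables).
#' @param tide_period_h Semidiurnal period (h), default the M2 constituent
#'   12.42.
#' @param tide_amp_mean,tide_amp_mod,spring_neap_d Mean semi-amplitude (m),
#'   spring-neap modulation (m) and its period (days).
#' @param det_d50,det_shape Logistic detection: distance of 50% detection
#'   and shape (m); effective range (p ~ 0.1) is about
#'   `det_d50 + 2.2 * det_shape`.
#' @param det_tide_mod Relative change of `det_d50` per unit of normalized
#'   tide height (tide-modulated detectability).
#' @param emission Transmitter emission interval bounds (s).
#' @param sst_min,sst_max Seasonal SST extremes (degC; min in August, max in
#'   February).
#' @param grid_dt Movement simulation step (s).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(study_start = as.Date("2019-11-01"),
                         study_days = 497,
                         inlet_length = 15000, inlet_width = 500,
                         receiver_x = seq(6500, 14500, by = 2000),
                         n_females = 11, n_males = 7,
                         q_peak_month = 12, q_max = 0.85, q_min = 0.10,
                         sex_differences = TRUE,
                         male_departure_window = c(100, 118),
                         female_daily_hazard = 0.004,
                         female_hazard_start = 90,
                         ou_center = 10500, ou_sd_x = 2500, ou_sd_y = 90,
                         ou_tau = 7200,
                         male_tide_drift = 4000,
                         tide_period_h = 12.42,
                         tide_amp_mean = 2.0, tide_amp_mod = 0.8,
                         spring_neap_d = 14.77,
                         det_d50 = 250, det_shape = 50, det_tide_mod = 0.1,
                         emission = c(60, 180),
                         sst_min = 8, sst_max = 18,
                         grid_dt = 300) {
  sc <- list(study_start = as.Date(study_start), study_days = study_days,
             inlet_length = inlet_length, inlet_width = inlet_width,
             receiver_x = receiver_x,
             n_females = n_females, n_males = n_males,
             q_peak_month = q_peak_month, q_max = q_max, q_min = q_min,
             sex_differences = sex_differences,
             male_departure_window = male_departure_window,
             female_daily_hazard = female_daily_hazard,
             female_hazard_start = female_hazard_start,
             ou_center = ou_center, ou_sd_x = ou_sd_x, ou_sd_y = ou_sd_y,
             ou_tau = ou_tau, male_tide_drift = male_tide_drift,
             tide_period_h = tide_period_h, tide_amp_mean = tide_amp_mean,
             tide_amp_mod = tide_amp_mod, spring_neap_d = spring_neap_d,
             det_d50 = det_d50, det_shape = det_shape,
             det_tide_mod = det_tide_mod, emission = emission,
             sst_min = sst_min, sst_max = sst_max, grid_dt = grid_dt)
  stopifnot(sc$study_days > 0, sc$q_max <= 1, sc$q_min >= 0,
            sc$q_min <= sc$q_max, all(sc$emission > 0),
            sc$emission[1] < sc$emission[2], sc$det_d50 > 0,
            sc$ou_tau > 0, sc$grid_dt > 0)
  if (any(receiver_x < 0 | receiver_x > inlet_length))
    stop("receiver positions fall outside the inlet")
  class(sc) <- "sim_scenario"
  sc
}

#' Seasonal occupancy curve
#'
#' Daily presence probability by calendar month: a raised cosine peaking at
#' `q_peak_month`.
#'
#' @param month Integer months 1-12.
#' @param scenario A [sim_scenario()].
#' @return Probabilities in `[q_min, q_max]`.
#' @export
occupancy_q <- function(month, scenario) {
  scenario$q_min + (scenario$q_max - scenario$q_min) *
    (1 + cos(2 * pi * (month - scenario$q_peak_month) / 12)) / 2
}

# Tide height (m) at time t (seconds since study start, numeric).
sim_tide_height <- function(t_sec, sc) {
  amp <- sc$tide_amp_mean + sc$tide_amp_mod *
    cos(2 * pi * t_sec / (sc$spring_neap_d * 86400))
  amp * cos(2 * pi * t_sec / (sc$tide_period_h * 3600))
}

#' Draw transmitter emission intervals
#'
#' Uniform on the programmed emission bounds, the behaviour of coded
#' transmitters with a randomized delay.
#'
#' @param n Number of intervals.
#' @param emission Bounds in seconds.
#' @return Numeric vector of intervals (s).
#' @export
remission_intervals <- function(n, emission = c(60, 180)) {
  stats::runif(n, emission[1], emission[2])
}

#' Simulate a gate-array telemetry dataset
#'
#' Generates, for a [sim_scenario()]: daily presence from the seasonal
#' occupancy curve with sex-specific permanent departure (abrupt for males,
#' gradual hazard for females), OU movement along the inlet while present
#' (tide-height-dependent drift toward the upper flats for males),
#' transmissions at uniform random emission intervals, and per-receiver
#' logistic distance-dependent detection. Every latent quantity is recorded
#' in `truth`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (mandatory: the simulation is only defined
#'   jointly with it).
#' @return A `sim_telemetry` list: `detections` (a [detection_table()]),
#'   `receivers`, `tags`, `tide` (a [tide_extremes()]), `sst`, `water`
#'   (a [water_polygon()]), `config` (a [study_config()]), `truth`, `seed`.
#' @export
simulate_telemetry <- function(scenario, seed) {
  if (missing(seed)) stop("seed is mandatory")
  sc <- scenario
  set.seed(seed)
  cfg <- study_config(sc$study_start, sc$study_start + sc$study_days)
  days <- seq(cfg$study_start, cfg$study_end, by = "day")
  nd <- length(days)
  month <- as.integer(format(days, "%m"))
  t0 <- as.numeric(as.POSIXct(cfg$study_start, tz = "UTC")) -
    cfg$local_utc_offset * 3600   # local midnight of day 1, as UTC epoch

  receivers <- data.frame(
    receiver_id = sprintf("R%02d", seq_along(sc$receiver_x)),
    x = sc$receiver_x, y = sc$inlet_width / 2,
    deploy_date = cfg$study_start - 3, recover_date = cfg$study_end + 1,
    status = "active", stringsAsFactors = FALSE)

  n_tags <- sc$n_females + sc$n_males
  tags <- data.frame(
    tag_id = sprintf("T%02d", seq_len(n_tags)),
    sex = c(rep("female", sc$n_females), rep("male", sc$n_males)),
    total_length = round(stats::runif(n_tags, 183, 245)),
    tagging_date = cfg$study_start - sample(1:3, n_tags, replace = TRUE),
    emission_min = sc$emission[1], emission_max = sc$emission[2],
    stringsAsFactors = FALSE)

  # permanent departure day (Inf = stays past study end)
  departure <- vapply(seq_len(n_tags), function(i) {
    male_like <- tags$sex[i] == "male" && sc$sex_differences
    if (male_like) {
      stats::runif(1, sc$male_departure_window[1], sc$male_departure_window[2])
    } else {
      h <- stats::rbinom(nd, 1, sc$female_daily_hazard)
      h[seq_len(min(sc$female_hazard_start, nd))] <- 0
      w <- which(h == 1)
      if (length(w)) as.numeric(w[1]) else Inf
    }
  }, numeric(1))

  # daily presence
  q <- occupancy_q(month, sc)
  present <- matrix(FALSE, n_tags, nd)
  for (i in seq_len(n_tags)) {
    alive <- seq_len(nd) < departure[i]
    present[i, ] <- alive & (stats::runif(nd) < q)
  }

  a <- exp(-sc$grid_dt / sc$ou_tau)
  sd_step_x <- sc$ou_sd_x * sqrt(1 - a^2)
  sd_step_y <- sc$ou_sd_y * sqrt(1 - a^2)
  max_amp <- sc$tide_amp_mean + sc$tide_amp_mod

  det_list <- list()
  for (i in seq_len(n_tags)) {
    pd <- which(present[i, ])
    if (!length(pd)) next
    male_drift <- tags$sex[i] == "male" && sc$sex_differences &&
      sc$male_tide_drift > 0
    bout_id <- cumsum(c(1, diff(pd) > 1))
    for (b in unique(bout_id)) {
      bd <- pd[bout_id == b]
      start_s <- (bd[1] - 1) * 86400
      end_s <- bd[length(bd)] * 86400
      gt <- seq(start_s, end_s, by = sc$grid_dt)
      h <- sim_tide_height(gt, sc)
      m_x <- if (male_drift) {
        # males ride the tide up toward the flats: at full high water they
        # share the common centre, at low water they sit well below it
        sc$ou_center - sc$male_tide_drift * (1 - h / max_amp)
      } else rep(sc$ou_center, length(gt))
      x0 <- stats::rnorm(1, m_x[1], sc$ou_sd_x)
      ux <- (1 - a) * m_x + stats::rnorm(length(gt), 0, sd_step_x)
      xx <- as.numeric(stats::filter(ux, a, "recursive", init = x0))
      uy <- (1 - a) * sc$inlet_width / 2 +
        stats::rnorm(length(gt), 0, sd_step_y)
      yy <- as.numeric(stats::filter(uy, a, "recursive",
                                     init = sc$inlet_width / 2))
      xx <- pmin(pmax(xx, 25), sc$inlet_length - 25)
      yy <- pmin(pmax(yy, 10), sc$inlet_width - 10)
      # transmissions
      n_tx_max <- ceiling((end_s - start_s) / sc$emission[1]) + 1
      tx <- start_s + cumsum(remission_intervals(n_tx_max, sc$emission))
      tx <- tx[tx < end_s]
      if (!length(tx)) next
      px <- stats::approx(gt, xx, xout = tx)$y
      py <- stats::approx(gt, yy, xout = tx)$y
      h_tx <- sim_tide_height(tx, sc)
      d50_eff <- sc$det_d50 * (1 + sc$det_tide_mod * h_tx / max_amp)
      for (r in seq_len(nrow(receivers))) {
        d <- sqrt((px - receivers$x[r])^2 + (py - receivers$y[r])^2)
        p <- 1 / (1 + exp((d - d50_eff) / sc$det_shape))
        hit <- stats::runif(length(tx)) < p
        if (any(hit))
          det_list[[length(det_list) + 1]] <- data.frame(
            t = tx[hit], tag = tags$tag_id[i],
            rec = receivers$receiver_id[r], stringsAsFactors = FALSE)
      }
    }
  }
  dets <- do.call(rbind, det_list)
  if (is.null(dets)) dets <- data.frame(t = numeric(), tag = character(),
                                        rec = character())
  det <- detection_table(
    as.POSIXct(t0 + dets$t, origin = "1970-01-01", tz = "UTC"),
    dets$tag, dets$rec, cfg)

  # tide extremes: successive half-period instants (cosine phase 0 / pi)
  half <- sc$tide_period_h * 3600 / 2
  k <- seq(-2, ceiling((sc$study_days + 2) * 86400 / half))
  te_t <- k * half
  amp <- sc$tide_amp_mean + sc$tide_amp_mod *
    cos(2 * pi * te_t / (sc$spring_neap_d * 86400))
  tide <- tide_extremes(
    as.POSIXct(t0 + te_t, origin = "1970-01-01", tz = "UTC"),
    ifelse(k %% 2 == 0, amp, -amp),
    ifelse(k %% 2 == 0, "high", "low"))

  sst_days <- seq(cfg$study_start - 1, cfg$study_end + 1, by = "day")
  doy <- as.integer(format(sst_days, "%j"))
  mid <- (sc$sst_min + sc$sst_max) / 2
  sst <- data.frame(date = sst_days,
                    sst_c = mid + (sc$sst_max - mid) *
                      cos(2 * pi * (doy - 46) / 365.25))

  water <- water_polygon(rbind(c(0, 0), c(sc$inlet_length, 0),
                               c(sc$inlet_length, sc$inlet_width),
                               c(0, sc$inlet_width)))

  truth <- list(scenario = unclass(sc), seed = seed,
                departure_day = stats::setNames(departure, tags$tag_id),
                q_by_month = stats::setNames(occupancy_q(1:12, sc),
                                             1:12),
                present_days = stats::setNames(rowSums(present), tags$tag_id))

  structure(list(detections = det, receivers = receivers, tags = tags,
                 tide = tide, sst = sst, water = water, config = cfg,
                 truth = truth, seed = seed),
            class = "sim_telemetry")
}

#' @export
print.sim_telemetry <- function(x, ...) {
  cat(sprintf("Simulated telemetry: %d detections, %d tags, %d receivers, %d days (seed %d)\n",
              nrow(x$detections), nrow(x$tags), nrow(x$receivers),
              study_duration_days(x$config), x$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the file formats the readers in this package consume:
#' `detections.csv`, `receivers.csv`, `tags.csv`, `tide.csv`, `sst.csv`,
#' `water.geojson` and `truth.json`.
#'
#' @param sim A [simulate_telemetry()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(sim$detections, file.path(dir, "detections.csv"))
  utils::write.csv(sim$receivers, file.path(dir, "receivers.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$tags, file.path(dir, "tags.csv"), row.names = FALSE)
  tide_out <- data.frame(
    time = format(sim$tide$time, "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
    height = sim$tide$height, kind = sim$tide$kind)
  utils::write.csv(tide_out, file.path(dir, "tide.csv"), row.names = FALSE)
  utils::write.csv(sim$sst, file.path(dir, "sst.csv"), row.names = FALSE)
  ring <- rbind(unclass(sim$water), unclass(sim$water)[1, ])
  gj <- list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)), function(i)
               as.numeric(ring[i, ]))))
  jsonlite::write_json(gj, file.path(dir, "water.geojson"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
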
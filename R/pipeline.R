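#' Read a full dataset directory
#'
#' Reads the canonical file layout (as written by [write_simulation()]):
#' `detections.csv`, `receivers.csv`, `tags.csv`, `tide.csv`, `sst.csv` and
#' `water.geojson` (any of the optional pieces may be absent).
#'
#' @param dir Directory path.
#' @param config A [study_config()] for the study window.
#' @return List with `detections`, `receivers`, `tags`, `tide`, `sst`,
#'   `water`, `config`.
#' @export
read_dataset <- function(dir, config) {
  pth <- function(f) file.path(dir, f)
  if (!file.exists(pth("detections.csv")))
    stop("no detections.csv in ", dir)
  receivers <- if (file.exists(pth("receivers.csv")))
    read_receivers(pth("receivers.csv")) else NULL
  tags <- if (file.exists(pth("tags.csv"))) read_tags(pth("tags.csv")) else NULL
  list(detections = read_detections(pth("detections.csv"), config,
                                    receivers = receivers, tags = tags),
       receivers = receivers, tags = tags,
       tide = if (file.exists(pth("tide.csv")))
         read_tide_extremes(pth("tide.csv")) else NULL,
       sst = if (file.exists(pth("sst.csv"))) read_sst(pth("sst.csv")) else NULL,
       water = if (file.exists(pth("water.geojson")))
         read_water_polygon(pth("water.geojson")) else NULL,
       config = config)
}

as_dataset <- function(data) {
  if (inherits(data, "sim_telemetry"))
    return(data[c("detections", "receivers", "tags", "tide", "sst", "water",
                  "config")])
  need <- c("detections", "tags", "config")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks: ", paste(miss, collapse = ", "))
  data
}

#' Run the seasonal analysis arm
#'
#' Curation, daily presence, residency/roaming indices, bouts,
#' detected/remaining proportions (overall and by sex), monthly receiver
#' profiles, the seasonal-detection and roaming model tables with their
#' AICc-ranked candidate fits, and (optionally) sex-specific water-masked
#' dBBMM space use with 50% contour overlap.
#'
#' @param data A `sim_telemetry` or a list as returned by [read_dataset()].
#' @param tagging_days `Date` vector passed to curation (default: the three
#'   days before the study start).
#' @param candidates_seasonal,candidates_roaming Named formula lists
#'   (defaults: [candidate_models()]); pass a shorter list to trade
#'   completeness for speed.
#' @param do_spaceuse Compute the dBBMM stage (default `TRUE`).
#' @param ud_cell,ud_delta dBBMM grid cell and location error (m).
#' @param out_dir Optional output directory; when given, the result tables
#'   are written as CSVs together with a `manifest.json` recording
#'   parameters and file checksums.
#' @return List of all stage outputs.
#' @export
run_seasonal <- function(data, tagging_days = NULL,
                         candidates_seasonal = NULL, candidates_roaming = NULL,
                         do_spaceuse = TRUE, ud_cell = 50, ud_delta = 200,
                         out_dir = NULL) {
  data <- as_dataset(data)
  cfg <- data$config
  if (is.null(tagging_days))
    tagging_days <- seq(cfg$study_start - 3, cfg$study_start - 1, by = "day")
  cur <- curate_detections(data$detections, tagging_days = tagging_days)
  p <- build_presence(cur$detections,
                      receivers = if (!is.null(data$receivers))
                        data$receivers$receiver_id else NULL)
  res <- residency_indices(p)
  roam <- roaming_index(p)
  bt <- bouts(p)
  props <- list(all = remaining_proportion(p),
                female = remaining_proportion(p, "female", data$tags),
                male = remaining_proportion(p, "male", data$tags))
  profile <- monthly_receiver_profile(p)
  amp <- if (!is.null(data$tide)) daily_amplitude(data$tide, cfg) else NULL
  seas_tab <- build_seasonal_table(p, data$tags, data$sst, amp)
  roam_tab <- build_roaming_table(p, data$tags, data$sst, amp)
  seas_fit <- fit_candidates(seas_tab, candidates_seasonal, kind = "seasonal")
  roam_fit <- fit_candidates(roam_tab, candidates_roaming, kind = "roaming")
  space <- NULL
  if (do_spaceuse && !is.null(data$receivers)) {
    space <- list()
    tracks <- build_tracks(cur$detections, data$receivers)
    tracks <- motion_variance(tracks, delta = ud_delta)
    for (sx in c("female", "male")) {
      ids <- data$tags$tag_id[data$tags$sex == sx]
      tr <- tracks[tracks$tag_id %in% ids, , drop = FALSE]
      if (!nrow(tr)) next
      space[[sx]] <- dbbmm_ud(tr, water = data$water, cell = ud_cell,
                              delta = ud_delta)
    }
    if (!is.null(space$female) && !is.null(space$male)) {
      cf <- ud_contour(space$female); cm <- ud_contour(space$male)
      ov <- ud_overlap(cf, cm)
      space$contours <- list(female = cf, male = cm)
      space$overlap <- c(female_in_male = unname(ov["a_in_b"]),
                         male_in_female = unname(ov["b_in_a"]))
    }
  }
  out <- list(curation = cur$report, presence = p, residency = res,
              roaming = roam, bouts = bt, proportions = props,
              monthly_profile = profile,
              seasonal_table = seas_tab, roaming_table = roam_tab,
              seasonal_models = seas_fit, roaming_models = roam_fit,
              spaceuse = space, config = cfg)
  if (!is.null(out_dir)) write_bundle(out, out_dir, arm = "seasonal")
  out
}

#' Run the intra-day analysis arm
#'
#' Hourly detection profiles, Rao spacing tests per tag and the Rao
#' homogeneity test across tags, average-linkage clustering of the
#' profiles, the hourly tide covariates, and the intra-day detection model
#' table with its AICc-ranked candidate fits.
#'
#' @inheritParams run_seasonal
#' @param candidates_intraday Named formula list (default
#'   [candidate_models()]).
#' @param n_mc,seed Monte-Carlo settings for the Rao spacing tests.
#' @return List of all stage outputs.
#' @export
run_intraday <- function(data, tagging_days = NULL,
                         candidates_intraday = NULL,
                         n_mc = 10000, seed = 1,
                         out_dir = NULL) {
  data <- as_dataset(data)
  cfg <- data$config
  if (is.null(data$tide)) stop("intra-day analysis requires tide extremes")
  if (is.null(tagging_days))
    tagging_days <- seq(cfg$study_start - 3, cfg$study_start - 1, by = "day")
  cur <- curate_detections(data$detections, tagging_days = tagging_days)
  det <- cur$detections
  profiles <- hourly_profiles(det)
  angles <- split(hour_angles(det), det$tag_id)
  set.seed(seed)
  null_u <- rao_spacing_null_by_n(vapply(angles, length, integer(1)), n_mc)
  spacing <- lapply(names(angles), function(tg) {
    a <- angles[[tg]]
    u <- rao_spacing_u(a)
    list(tag_id = tg, n = length(a), U = u,
         p_value = mean(null_u[[as.character(length(a))]] >= u))
  })
  spacing <- do.call(rbind, lapply(spacing, as.data.frame))
  homog <- if (length(angles) >= 2) rao_homogeneity_test(angles) else NULL
  clust <- cluster_profiles(profiles, k = 2)
  p <- build_presence(det,
                      receivers = if (!is.null(data$receivers))
                        data$receivers$receiver_id else NULL)
  tide_cov <- tide_covariates(data$tide)
  intra_tab <- build_intraday_table(det, p, tide_cov, data$tags)
  intra_fit <- fit_candidates(intra_tab, candidates_intraday,
                              kind = "intraday")
  out <- list(curation = cur$report, profiles = profiles,
              spacing_tests = spacing, homogeneity = homog,
              clustering = clust, tide_covariates = tide_cov,
              intraday_table = intra_tab, intraday_models = intra_fit,
              config = cfg)
  if (!is.null(out_dir)) write_bundle(out, out_dir, arm = "intraday")
  out
}

# Shared null distributions of the Rao spacing U per distinct sample size.
rao_spacing_null_by_n <- function(ns, n_mc) {
  out <- list()
  for (n in unique(ns[ns >= 2]))
    out[[as.character(n)]] <- rao_spacing_null(n, n_mc)
  out
}

write_bundle <- function(out, dir, arm) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(x, name) {
    f <- file.path(dir, name)
    utils::write.csv(x, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (arm == "seasonal") {
    wr(out$residency, "residency.csv")
    wr(data.frame(tag_id = names(out$roaming), roaming = out$roaming),
       "roaming.csv")
    wr(out$bouts, "bouts.csv")
    wr(out$proportions$all, "remaining_proportion.csv")
    wr(out$monthly_profile, "monthly_receiver_profile.csv")
    wr(out$seasonal_models$ranking, "seasonal_model_ranking.csv")
    wr(out$roaming_models$ranking, "roaming_model_ranking.csv")
    # abacus-style long table (tag x day presence) for plotting
    ab <- which(out$presence$presence, arr.ind = TRUE)
    wr(data.frame(tag_id = out$presence$tags[ab[, 1]],
                  day = out$presence$days[ab[, 2]]), "abacus.csv")
    if (!is.null(out$spaceuse$overlap))
      wr(data.frame(direction = names(out$spaceuse$overlap),
                    overlap_pct = as.numeric(out$spaceuse$overlap)),
         "ud_overlap.csv")
  } else {
    pr <- as.data.frame(as.table(out$profiles))
    names(pr) <- c("tag_id", "hour", "proportion")
    pr$cluster <- out$clustering$labels[as.character(pr$tag_id)]
    wr(pr, "hourly_profiles.csv")
    wr(out$spacing_tests, "rao_spacing.csv")
    wr(out$tide_covariates, "tide_covariates.csv")
    wr(out$intraday_models$ranking, "intraday_model_ranking.csv")
  }
  manifest <- list(arm = arm,
                   n_input = out$curation$n_input,
                   n_curated = out$curation$n_output,
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Parameter-recovery report for a simulated dataset
#'
#' Runs the analysis pipeline on a [simulate_telemetry()] output and
#' compares what it recovers against the simulator's recorded truth:
#' monthly detected/remaining proportions vs the occupancy curve, the peak
#' month of the fitted cyclic month smooth, the sex contrast in departure
#' abruptness, and the direction of the intra-day tide-height effect for
#' males.
#'
#' @param sim A [simulate_telemetry()] result.
#' @param fit_intraday Also fit the intra-day tide model (slower); default
#'   `TRUE`.
#' @return List with `monthly` (recovered vs true occupancy by month),
#'   `peak_month` (of the fitted month smooth, per sex), `departure`
#'   (last-detection spread by sex), `sexmonth_p` (p-value of the
#'   month-by-sex smooth), and optionally `tide_male` (male high-vs-low
#'   linear-predictor contrast).
#' @export
recovery_report <- function(sim, fit_intraday = TRUE) {
  cfg <- sim$config
  tagging_days <- seq(cfg$study_start - 3, cfg$study_start - 1, by = "day")
  cur <- curate_detections(sim$detections, tagging_days = tagging_days)
  p <- build_presence(cur$detections,
                      receivers = sim$receivers$receiver_id)
  rp <- remaining_proportion(p)
  mo <- as.integer(format(rp$day, "%m"))
  monthly <- data.frame(
    month = sort(unique(mo)),
    recovered = as.numeric(tapply(rp$proportion, mo, mean, na.rm = TRUE)),
    truth = sim$truth$q_by_month[as.character(sort(unique(mo)))])

  amp <- daily_amplitude(sim$tide, cfg)
  tab <- build_seasonal_table(p, sim$tags, sim$sst, amp)
  fit_sex <- fit_binomial_gam(tab,
    detected ~ sex + s(month, bs = "cc", k = 6) +
      s(month, by = sex, bs = "cc", k = 6) + s(tag, bs = "re"))
  fit_null <- fit_binomial_gam(tab,
    detected ~ sex + s(month, bs = "cc", k = 6) + s(tag, bs = "re"))
  grid <- data.frame(month = seq(1, 12.99, by = 0.01),
                     sex = factor("female", levels = c("female", "male")),
                     tag = factor(tab$tag[1], levels = levels(tab$tag)))
  sm <- evaluate_smooth(fit_sex, "s(month)", grid)
  peak <- grid$month[which.max(sm)]
  smry <- summary(fit_sex$model)
  sx_rows <- grep("s\\(month\\):sex", rownames(smry$s.table))
  sexmonth_p <- if (length(sx_rows)) min(smry$s.table[sx_rows, "p-value"]) else NA

  last <- tapply(local_day(cur$detections$timestamp, cfg),
                 cur$detections$tag_id, max)
  last <- stats::setNames(as.Date(as.numeric(last), origin = "1970-01-01"),
                          names(last))
  sx <- sim$tags$sex[match(names(last), sim$tags$tag_id)]
  departure <- data.frame(
    sex = c("female", "male"),
    n = c(sum(sx == "female"), sum(sx == "male")),
    mean_last_day = c(mean(as.numeric(last[sx == "female"] - cfg$study_start)),
                      mean(as.numeric(last[sx == "male"] - cfg$study_start))),
    sd_last_day = c(stats::sd(as.numeric(last[sx == "female"])),
                    stats::sd(as.numeric(last[sx == "male"]))))

  out <- list(monthly = monthly, peak_month = peak,
              sexmonth_p = sexmonth_p,
              fit_sexmonth = fit_sex, fit_nullmonth = fit_null,
              departure = departure)

  if (fit_intraday) {
    tide_cov <- tide_covariates(sim$tide)
    itab <- build_intraday_table(cur$detections, p, tide_cov, sim$tags)
    ifit <- fit_binomial_gam(itab,
      detected ~ sex + height_class + height_class:sex + s(tag, bs = "re"))
    if (!is.null(ifit$model)) {
      nd <- data.frame(sex = factor("male", levels = c("female", "male")),
                       height_class = factor(c("high", "low"),
                                             levels = c("low", "intermediate",
                                                        "high")),
                       tag = factor(itab$tag[1], levels = levels(itab$tag)))
      lp <- stats::predict(ifit$model, nd, type = "link",
                           exclude = "s(tag)")
      out$tide_male <- c(high_minus_low = unname(lp[1] - lp[2]))
      out$fit_intraday <- ifit
    }
  }
  out
}

#' Reproduce the field-study residency summary from deposited data
#'
#' Runs the curation chain (collision proxy, daily singletons, the three
#' tagging days, the first-5-days rule, stationary-tag exclusion) and the
#' residency statistics on a deposited detection dataset laid out as a
#' [read_dataset()] directory, with the historical study window of
#' 1 November 2019 - 12 March 2021. Returns the summary quantities that a
#' successful reproduction should match against the published study:
#' number of analyzed individuals, mean minimum/maximum residency, mean
#' detection period, and mean presence/absence bout lengths.
#'
#' @param dir Directory holding the deposited data in `read_dataset()`
#'   layout.
#' @param config Study window (default the historical one).
#' @param tagging_days Tagging days to drop (default 29-31 October 2019).
#' @return List of summary statistics.
#' @export
reproduce_field_study <- function(dir,
                                  config = study_config("2019-11-01",
                                                        "2021-03-12"),
                                  tagging_days = seq(as.Date("2019-10-29"),
                                                     as.Date("2019-10-31"),
                                                     by = "day")) {
  data <- read_dataset(dir, config)
  cur <- curate_detections(data$detections, tagging_days = tagging_days,
                           exclude_stationary = TRUE)
  p <- build_presence(cur$detections)
  res <- residency_indices(p)
  bt <- bouts(p)
  list(n_individuals = nrow(res),
       mean_min_residency = mean(res$min_residency),
       mean_max_residency = mean(res$max_residency),
       mean_detection_period = mean(as.numeric(res$last_day - res$first_day) + 1),
       mean_presence_bout = mean(bt$length[bt$type == "presence"]),
       mean_absence_bout = mean(bt$length[bt$type == "absence"]),
       curation = cur$report)
}
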
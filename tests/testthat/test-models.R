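test_that("AICc correction behaves across its range", {
  expect_equal(aicc(50, 2, 100), 50 + 12 / 97)
  expect_equal(aicc(100, 0.5, 10), 100 + 2 * 0.5 * 1.5 / 8.5)
  # k approaching n - 1 blows up
  expect_equal(aicc(50, 99, 100), Inf)
  expect_gt(aicc(50, 5, 100), aicc(50, 5, 1000))
})

test_that("aicc_rank orders fits and handles non-convergence", {
  mk <- function(aic, k, n, conv = TRUE)
    structure(list(aic = aic, aicc = aicc(aic, k, n), k = k, n = n,
                   dev_expl = 0.1, converged = conv), class = "tg_gam")
  fits <- list(a = mk(52, 3, 100), b = mk(50, 3, 100), c = mk(50, 3, 100))
  r <- aicc_rank(fits)
  expect_equal(r$model[1:2], c("b", "c"))
  expect_equal(r$delta_aicc[1:2], c(0, 0))   # two equal fits tie at delta 0
  expect_equal(r$delta_aicc[3], 2)
  expect_warning(r2 <- aicc_rank(list(a = mk(50, 3, 100),
                                      bad = mk(40, 3, 100, conv = FALSE))),
                 "non-converged")
  expect_equal(r2$model[1], "a")
  expect_true(is.na(r2$delta_aicc[r2$model == "bad"]))
})

test_that("model tables are assembled with the stated row semantics", {
  cfg <- study_config("2020-01-01", "2020-06-30")
  # tag A: detections on days 1..100 (sparse), last detection day 100
  tr <- data.frame(day = c(0, 30, 99), tag = "A", rec = "R1")
  p <- make_presence(tr, cfg)
  tags <- data.frame(tag_id = "A", sex = "female", total_length = 200,
                     tagging_date = as.Date("2019-12-29"))
  tab <- build_seasonal_table(p, tags)
  expect_equal(nrow(tab), 100)              # rows through the last detection
  expect_equal(sum(tab$detected), 3)
  expect_equal(tab$detected[tab$day == as.Date("2020-01-31")], 1)
  expect_equal(tab$detected[tab$day == as.Date("2020-02-01")], 0)
  # missing SST days drop rows (with a message) under the default policy
  sst <- data.frame(date = seq(as.Date("2020-01-01"), by = "day",
                               length.out = 50), sst_c = 15)
  expect_message(tab2 <- build_seasonal_table(p, tags, sst = sst), "dropped")
  expect_equal(nrow(tab2), 50)

  # roaming rows exist only for present days, response sums to R
  tr2 <- rbind(data.frame(day = 1, tag = "A", rec = c("R1", "R2", "R3")),
               data.frame(day = 3, tag = "A", rec = "R1"))
  p2 <- make_presence(tr2, cfg)
  # no males in this toy study, so prop_m is undefined: keep rows to inspect
  rt <- build_roaming_table(p2, tags, R = 5, na_action = "keep")
  expect_true(all(is.na(rt$prop_m)))
  expect_equal(nrow(rt), 2)
  expect_equal(rt$visited[1], 3)
  expect_equal(rt$not_visited[1], 2)
  expect_true(all(rt$visited + rt$not_visited == 5))
})

test_that("intra-day tables expand present days into 24 hourly rows", {
  cfg <- study_config("2020-01-01", "2020-01-31")
  # one detection at 14:30 local = 17:30 UTC
  d <- make_det(c("2020-01-10 17:30:00", "2020-01-10 18:30:00"), "A", "R1",
                cfg)
  p <- build_presence(d)
  ex <- tide_extremes(
    as.POSIXct("2020-01-01 00:00", tz = "UTC") + seq(0, 40 * 86400, by = 6.21 * 3600),
    rep(c(3, -3), length.out = 155)[1:155],
    rep(c("high", "low"), length.out = 155)[1:155])
  tc <- tide_covariates(ex)
  tags <- data.frame(tag_id = "A", sex = "male", total_length = 210,
                     tagging_date = as.Date("2019-12-29"))
  tab <- build_intraday_table(d, p, tc, tags)
  expect_equal(nrow(tab), 24)               # one present day
  expect_equal(sum(tab$detected), 2)
  expect_equal(tab$detected[tab$hour == 14], 1)
  expect_equal(tab$detected[tab$hour == 20], 0)
  expect_true(all(c("height_class", "direction", "strength") %in% names(tab)))
})

test_that("a cyclic month smooth recovers a known seasonal signal", {
  set.seed(21)
  n_tag <- 12; n_day <- 360
  month <- rep(1 + (seq_len(n_day) - 1) %/% 30, n_tag)
  month <- pmin(month, 12)
  tag <- factor(rep(sprintf("t%02d", seq_len(n_tag)), each = n_day))
  re <- stats::rnorm(n_tag, 0, 0.3)[as.integer(tag)]
  eta <- 1.2 * sin(2 * pi * (month - 9) / 12) + re
  tab <- data.frame(tag = tag, month = month,
                    detected = stats::rbinom(length(eta), 1,
                                             stats::plogis(eta)))
  fit <- fit_binomial_gam(tab, detected ~ s(month, bs = "cc", k = 6) +
                            s(tag, bs = "re"))
  expect_true(fit$converged)
  grid <- data.frame(month = seq(1, 12.99, by = 0.01),
                     tag = factor("t01", levels = levels(tag)))
  sm <- evaluate_smooth(fit, "s(month)", grid)
  truth_peak <- 12   # sin peaks at month - 9 = 3 (mod 12)
  est_peak <- grid$month[which.max(sm)]
  dist <- min(abs(est_peak - truth_peak), 12 - abs(est_peak - truth_peak))
  expect_lt(dist, 1)
  # periodicity: the smooth joins at the year boundary
  ends <- evaluate_smooth(fit, "s(month)",
                          data.frame(month = c(0.5001, 12.4999),
                                     tag = factor("t01",
                                                  levels = levels(tag))))
  expect_equal(ends[1], ends[2], tolerance = 1e-2)
})

test_that("penalization shrinks a null covariate to near-zero complexity", {
  set.seed(8)
  n <- 800
  tab <- data.frame(x = stats::runif(n), noise = stats::runif(n))
  tab$detected <- stats::rbinom(n, 1, stats::plogis(2 * tab$x - 1))
  fit <- fit_binomial_gam(tab, detected ~ s(x, k = 6) + s(noise, k = 6),
                          select = TRUE)
  sm <- summary(fit$model)$s.table
  expect_lt(sm["s(noise)", "edf"], 0.5)
  expect_gt(sm["s(x)", "edf"], 0.5)
})

test_that("candidate sets contain the documented nesting structure", {
  for (kind in c("seasonal", "roaming", "intraday")) {
    cm <- candidate_models(kind)
    expect_gte(length(cm), 4)
    txt <- vapply(cm, function(f) paste(deparse(f), collapse = " "),
                  character(1))
    expect_true(any(grepl("tag_sex|tag", txt)))        # RE variants
    expect_true(any(!grepl("s\\(tag", txt)))           # a no-RE variant
  }
})
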
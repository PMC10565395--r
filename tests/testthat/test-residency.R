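short_cfg <- function(days = 30)
  study_config("2020-01-01", as.Date("2020-01-01") + days)

test_that("presence matrix records local days and receiver sets", {
  cfg <- short_cfg()
  d <- make_det("2020-01-10 12:00:00", "A", "R2", cfg)
  p <- build_presence(d)
  expect_true(p$presence["A", "2020-01-10"])
  expect_equal(sum(p$presence), 1)
  expect_true(p$by_receiver["A", "2020-01-10", "R2"])
  # straddling the local midnight: 23:59 and 00:01 local are two days
  # (local = UTC - 3 h, so 02:59 and 03:01 UTC)
  d2 <- make_det(c("2020-01-10 02:59:00", "2020-01-10 03:01:00"), "A", "R1",
                 cfg)
  p2 <- build_presence(d2)
  expect_true(p2$presence["A", "2020-01-09"])
  expect_true(p2$presence["A", "2020-01-10"])
  # no detections
  p3 <- build_presence(d[0, ], tags = "A", receivers = "R1")
  expect_false(any(p3$presence))
})

test_that("residency indices bracket the detection history", {
  cfg <- short_cfg(30)
  # detected every day of a 10-day span
  p <- make_presence(data.frame(day = 5:14, tag = "A", rec = "R1"), cfg)
  r <- residency_indices(p)
  expect_equal(r$max_residency, 1)
  expect_equal(r$min_residency, 10 / 30)
  expect_equal(r$days_detected, 10)
  # detected on days {d, d+9} only: span oracle gives 2/10
  p2 <- make_presence(data.frame(day = c(3, 12), tag = "A", rec = "R1"), cfg)
  expect_equal(residency_indices(p2)$max_residency, 2 / 10)
  # arithmetic: 100 detected days over the historical 497-day study
  cfg497 <- hist_cfg()
  p3 <- make_presence(data.frame(day = seq(0, 396, by = 4), tag = "A",
                                 rec = "R1"), cfg497)
  expect_equal(residency_indices(p3)$min_residency, 100 / 497)
})

test_that("min residency never exceeds max residency", {
  cfg <- short_cfg(20)
  set.seed(3)
  for (i in 1:20) {
    days <- sort(sample(0:20, sample(1:15, 1)))
    p <- make_presence(data.frame(day = days, tag = "A", rec = "R1"), cfg)
    r <- residency_indices(p)
    expect_lte(r$min_residency, r$max_residency)
  }
  # equality iff the span covers the whole study window
  pfull <- make_presence(data.frame(day = c(0, 10, 20), tag = "A", rec = "R1"),
                         cfg)
  rf <- residency_indices(pfull)
  expect_equal(rf$min_residency, rf$max_residency)
  # strict inequality when the span falls short of the window
  ppart <- make_presence(data.frame(day = c(0, 10), tag = "A", rec = "R1"),
                         cfg)
  rp <- residency_indices(ppart)
  expect_lt(rp$min_residency, rp$max_residency)
})

test_that("roaming index averages the daily receiver fraction", {
  cfg <- short_cfg()
  # one receiver per present day, five receivers: exactly 0.2
  p1 <- make_presence(data.frame(day = 1:10, tag = "A", rec = "R1"), cfg)
  expect_equal(unname(roaming_index(p1, R = 5)), 0.2)
  # all five receivers every present day: exactly 1
  p5 <- make_presence(expand.grid(day = 1:4, tag = "A",
                                  rec = paste0("R", 1:5)), cfg)
  expect_equal(unname(roaming_index(p5, R = 5)), 1)
  # day 1: 2 receivers, day 2: 3 receivers -> 0.5
  tr <- rbind(data.frame(day = 1, tag = "A", rec = c("R1", "R2")),
              data.frame(day = 2, tag = "A", rec = c("R1", "R2", "R3")))
  expect_equal(unname(roaming_index(make_presence(tr, cfg), R = 5)), 0.5)
})

test_that("roaming index equals the brute-force day enumeration", {
  cfg <- short_cfg(10)
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    tr <- data.frame(day = sample(0:9, n, TRUE), tag = "A",
                     rec = sample(paste0("R", 1:5), n, TRUE))
    p <- make_presence(tr, cfg)
    oracle <- mean(vapply(split(tr$rec, tr$day),
                          function(r) length(unique(r)) / 5, numeric(1)))
    expect_equal(unname(roaming_index(p, R = 5)), oracle)
  }
})

test_that("residency categories follow the 0.1 / 0.5 thresholds", {
  got <- categorize_residency(c(0.05, 0.1, 0.3, 0.5, 0.69))
  expect_equal(as.character(got),
               c("vagrant", "short-term", "short-term", "short-term",
                 "long-term"))
})

test_that("bouts run-length encode the detection span", {
  cfg <- short_cfg()
  # presence 1,1,0,0,0,1 -> presence bouts {2,1}, absence {3}
  p <- make_presence(data.frame(day = c(2, 3, 7), tag = "A", rec = "R1"), cfg)
  b <- bouts(p)
  expect_equal(b$length[b$type == "presence"], c(2, 1))
  expect_equal(b$length[b$type == "absence"], 3)
  # all present: one bout, no absences
  b2 <- bouts(make_presence(data.frame(day = 4:8, tag = "A", rec = "R1"), cfg))
  expect_equal(nrow(b2[b2$type == "absence", ]), 0)
  expect_equal(b2$length, 5)
  # single day
  b3 <- bouts(make_presence(data.frame(day = 4, tag = "A", rec = "R1"), cfg))
  expect_equal(b3$length, 1)
})

test_that("bout lengths partition each tag's span", {
  cfg <- short_cfg(25)
  set.seed(5)
  for (i in 1:10) {
    days <- sort(unique(sample(0:25, sample(2:20, 1))))
    p <- make_presence(data.frame(day = days, tag = "A", rec = "R1"), cfg)
    b <- bouts(p)
    expect_equal(sum(b$length), max(days) - min(days) + 1)
  }
})

test_that("detected/remaining proportions drop departed tags", {
  cfg <- short_cfg(20)
  # two tags: A detected days 0..10, B only day 0..2
  tr <- rbind(data.frame(day = 0:10, tag = "A", rec = "R1"),
              data.frame(day = 0:2, tag = "B", rec = "R1"))
  p <- make_presence(tr, cfg)
  rp <- remaining_proportion(p)
  expect_equal(rp$n_remaining[rp$day == as.Date("2020-01-02")], 2)
  expect_equal(rp$proportion[rp$day == as.Date("2020-01-02")], 1)
  # the day after B's last detection it leaves the denominator
  expect_equal(rp$n_remaining[rp$day == as.Date("2020-01-04")], 1)
  # after everyone departs the proportion is NA, not zero
  expect_true(is.na(rp$proportion[rp$day == as.Date("2020-01-15")]))
  # appending post-departure empty days does not change earlier values
  cfg2 <- short_cfg(28)
  rp2 <- remaining_proportion(make_presence(tr, cfg2))
  expect_equal(rp2$proportion[1:20], rp$proportion[1:20])
})

test_that("monthly receiver profile tracks a faithful resident", {
  cfg <- study_config("2020-01-01", "2020-03-31")
  days <- 0:90
  p <- make_presence(data.frame(day = days, tag = "A", rec = "R1"), cfg)
  prof <- monthly_receiver_profile(p)
  r1 <- prof[prof$receiver_id == "R1", ]
  expect_true(all(r1$mean_proportion == 1))
})

test_that("the simulator's seasonal occupancy is recovered", {
  # detection made near-certain so the detected/remaining proportion
  # estimates the occupancy probability q directly; no departures
  sc <- sim_scenario(study_days = 150, n_females = 11, n_males = 11,
                     sex_differences = FALSE, female_daily_hazard = 0,
                     det_d50 = 8000, emission = c(1200, 2400),
                     q_max = 0.8, q_min = 0.2)
  sim <- simulate_telemetry(sc, seed = 7)
  cur <- curate_detections(sim$detections)
  p <- build_presence(cur$detections)
  rp <- remaining_proportion(p)
  mo <- as.integer(format(rp$day, "%m"))
  for (m in unique(mo)) {
    sel <- mo == m & !is.na(rp$proportion)
    est <- mean(rp$proportion[sel])
    se <- stats::sd(rp$proportion[sel]) / sqrt(sum(sel))
    q_true <- sim$truth$q_by_month[as.character(m)]
    expect_lt(abs(est - q_true), 3 * se + 0.02)
  }
})
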
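# Brute-force oracle for collision removal: pairwise scan marking every
# detection that has a different-tag neighbour at the same receiver within
# the window (strict), after exact-duplicate reduction.
collision_oracle <- function(det, window) {
  key <- paste(format(det$timestamp, "%Y-%m-%d %H:%M:%OS6"), det$tag_id,
               det$receiver_id)
  det <- det[!duplicated(key), , drop = FALSE]
  n <- nrow(det)
  drop <- rep(FALSE, n)
  if (window > 0 && n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (det$receiver_id[i] == det$receiver_id[j] &&
          det$tag_id[i] != det$tag_id[j] &&
          abs(as.numeric(det$timestamp[i]) -
              as.numeric(det$timestamp[j])) < window) {
        drop[i] <- TRUE; drop[j] <- TRUE
      }
    }
  }
  det[!drop, c("timestamp", "tag_id", "receiver_id")]
}

test_that("collision proxy removes near-simultaneous multi-tag groups", {
  d <- make_det(c("2020-01-05 10:00:00", "2020-01-05 10:00:00"),
                c("A", "B"), c("R1", "R1"))
  expect_equal(nrow(remove_collisions(d)), 0)
  # different receivers: both kept
  d2 <- make_det(c("2020-01-05 10:00:00", "2020-01-05 10:00:00"),
                 c("A", "B"), c("R1", "R2"))
  expect_equal(nrow(remove_collisions(d2)), 2)
  # window = 0: only exact duplicates removed
  d3 <- make_det(rep("2020-01-05 10:00:00", 3),
                 c("A", "A", "B"), c("R1", "R1", "R1"))
  out3 <- remove_collisions(d3, window = 0)
  expect_equal(nrow(out3), 2)
  expect_setequal(out3$tag_id, c("A", "B"))
})

test_that("collision removal matches the brute-force pairwise oracle", {
  cfg <- hist_cfg()
  set.seed(42)
  for (rep in 1:5) {
    n <- 60
    t0 <- as.POSIXct("2020-02-01 00:00:00", tz = "UTC")
    det <- detection_table(t0 + round(runif(n, 0, 40)),
                           sample(c("A", "B", "C"), n, TRUE),
                           sample(c("R1", "R2"), n, TRUE), cfg)
    for (w in c(0, 1, 3)) {
      got <- remove_collisions(det, w)
      want <- collision_oracle(det, w)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$timestamp, want$timestamp)
      expect_equal(got$tag_id, want$tag_id)
    }
  }
})

test_that("daily singletons are removed, larger day groups kept whole", {
  d <- make_det(c("2020-01-05 10:00:00", sprintf("2020-01-05 1%d:00:00", 1:5)),
                "A", c("R1", rep("R2", 5)))
  out <- remove_daily_singletons(d)
  expect_equal(nrow(out), 5)
  expect_true(all(out$receiver_id == "R2"))
  # exactly two detections: the boundary group survives
  d2 <- make_det(c("2020-01-05 01:00:00", "2020-01-05 02:00:00"), "A", "R1")
  expect_equal(nrow(remove_daily_singletons(d2)), 2)
  # empty in, empty out
  expect_equal(nrow(remove_daily_singletons(d2[0, ])), 0)
})

test_that("tagging-window days are dropped", {
  cfg <- study_config("2019-10-01", "2020-10-01")
  d <- make_det(c("2019-10-30 12:00:00", "2019-10-30 13:00:00",
                  "2019-11-01 12:00:00"), "A", "R1", cfg)
  out <- drop_tagging_window(d, seq(as.Date("2019-10-29"),
                                    as.Date("2019-10-31"), by = "day"))
  expect_equal(nrow(out), 1)
  expect_equal(local_day(out$timestamp, cfg), as.Date("2019-11-01"))
  expect_equal(nrow(drop_tagging_window(d, as.Date(character()))), 3)
})

test_that("tags detected only within the initial horizon are excluded", {
  cfg <- hist_cfg()
  # A: days 1-2 only; B: days 3 and 40
  d <- make_det(c("2019-11-01 12:00:00", "2019-11-02 12:00:00",
                  "2019-11-03 12:00:00", "2019-12-10 12:00:00"),
                c("A", "A", "B", "B"), "R1", cfg)
  out <- exclude_nonrepresentative_tags(d, horizon_days = 5)
  expect_equal(out$excluded$tag_id, "A")
  expect_setequal(unique(out$detections$tag_id), "B")
  # identity when every tag extends beyond the horizon
  d2 <- restrict_all <- out$detections
  out2 <- exclude_nonrepresentative_tags(d2, horizon_days = 5)
  expect_equal(nrow(out2$excluded), 0)
  expect_equal(nrow(out2$detections), nrow(d2))
})

test_that("stationary tags are flagged by single-receiver run length", {
  cfg <- hist_cfg()
  days60 <- as.character(seq(as.Date("2020-01-01"), by = "day", length.out = 60))
  d <- make_det(paste(days60, "12:00:00"), "A", "R3", cfg)
  expect_equal(flag_stationary_tags(d, min_span_days = 30), "A")
  # alternating receivers: not stationary
  d2 <- make_det(paste(days60, "12:00:00"), "B",
                 rep(c("R1", "R2"), 30), cfg)
  expect_equal(length(flag_stationary_tags(d2, min_span_days = 30)), 0)
  # required span longer than the history: not flagged
  expect_equal(length(flag_stationary_tags(d, min_span_days = 90)), 0)
  # run-length oracle: longest single-receiver streak decides the flag
  run <- rle(rep(TRUE, 60))
  expect_true(max(run$lengths) >= 30)
})

test_that("the curation chain is ordered, idempotent and subsetting", {
  sim <- fixture_sim()
  tagging <- seq(sim$config$study_start - 3, sim$config$study_start - 1,
                 by = "day")
  once <- curate_detections(sim$detections, tagging_days = tagging)
  twice <- curate_detections(once$detections, tagging_days = tagging)
  expect_equal(nrow(twice$detections), nrow(once$detections))
  expect_equal(twice$detections$timestamp, once$detections$timestamp)
  # no imputation: output rows all exist in the input
  key_in <- paste(format(sim$detections$timestamp, "%Y-%m-%d %H:%M:%OS6"),
                  sim$detections$tag_id, sim$detections$receiver_id)
  key_out <- paste(format(once$detections$timestamp, "%Y-%m-%d %H:%M:%OS6"),
                   once$detections$tag_id, once$detections$receiver_id)
  expect_true(all(key_out %in% key_in))
  # report counts are sum-consistent
  r <- once$report
  expect_equal(r$n_input - r$n_collision_removed - r$n_singleton_removed -
                 r$n_tagging_window_removed - r$n_nonrepresentative_removed -
                 r$n_stationary_removed,
               r$n_output)
})

test_that("collisions are removed before daily singletons", {
  # A collides with B at 10:00; A has one other hit that day. Removing the
  # collision first leaves that hit a singleton (removed); the reverse
  # order would keep it.
  d <- make_det(c("2020-01-05 10:00:00", "2020-01-05 10:00:00",
                  "2020-01-05 15:00:00"),
                c("A", "B", "A"), "R1")
  collision_first <- remove_daily_singletons(remove_collisions(d))
  singleton_first <- remove_collisions(remove_daily_singletons(d))
  expect_equal(nrow(collision_first), 0)
  expect_equal(nrow(singleton_first), 2)  # B's singleton goes, A keeps both
  chained <- curate_detections(d)
  expect_equal(nrow(chained$detections), 0)
  expect_equal(chained$report$n_collision_removed, 2)
  expect_equal(chained$report$n_singleton_removed, 1)
})
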
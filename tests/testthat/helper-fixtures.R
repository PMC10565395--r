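# Shared fixtures. The simulation is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

hist_cfg <- function() study_config("2019-11-01", "2021-03-12")

# A small but structurally complete simulated study: 7 tags, 4 months,
# slower transmitters to keep the detection table light.
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    sc <- sim_scenario(study_days = 120, n_females = 4, n_males = 3,
                       emission = c(300, 600))
    .fixture_env$sim <- simulate_telemetry(sc, seed = 101)
  }
  .fixture_env$sim
}

# Detection table from parallel vectors of timestamp strings (UTC).
make_det <- function(times, tags, recs, cfg = hist_cfg()) {
  detection_table(as.POSIXct(times, tz = "UTC"), tags, recs, cfg)
}

# Presence matrix built from (tag, day-offset, receiver) triples; day
# offsets are 0-based from study_start. Detections are doubled within a
# day so they survive curation if ever passed through it.
make_presence <- function(triples, cfg) {
  t0 <- as.POSIXct(cfg$study_start, tz = "UTC") - cfg$local_utc_offset * 3600
  times <- t0 + triples$day * 86400 + 12 * 3600 + seq_len(nrow(triples))
  det <- detection_table(times, triples$tag, triples$rec, cfg)
  build_presence(det)
}
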
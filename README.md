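# tidegate

Residency, tide and space-use analysis for **gate-array passive acoustic
telemetry** in narrow tidal inlets.

`tidegate` is aimed at movement ecologists who monitor tagged marine
animals (sharks, rays, large teleosts) with a line of omnidirectional
acoustic receivers spanning a narrow coastal inlet, where each receiver
acts as a "gate": its detection range covers the channel width, so passages
are registered even though positions are only known to receiver resolution.
The package covers the full analysis chain for such a study:

- **Curation** of raw detection logs: near-simultaneous multi-tag hits at
  one receiver (the operational proxy for code collisions), daily
  singletons, the post-tagging stress window, tags detected only in the
  first days of the study, and stationary tags suggesting shed
  transmitters.
- **Residency statistics** from the daily presence matrix. For a tag with
  `D` detected days, first/last detection span `S` (days, inclusive) and a
  study of `T` days, the *maximum residency index* is `D / S` and the
  *minimum residency index* is `D / T`; the pair brackets the unobservable
  true residency. The *roaming index* is the mean over present days of
  (receivers visited) / (receivers in the array), ranging from `1/R` to 1.
  Presence/absence bouts, residency categories (vagrant < 0.1 ≤ short-term
  ≤ 0.5 < long-term), and the departure-corrected *detected/remaining
  proportion* (overall and per sex) complete the set.
- **Tide covariates** from high/low-water tables: hourly heights by cosine
  interpolation, daily amplitude, height classes at the 0.25/0.75
  quantiles, inflow/outflow direction, weak/strong strength around slack
  water, and least-squares calibration (offset, scale, lag) against
  in-situ logger records.
- **Circular hour-of-day statistics**: Rao's spacing test of uniformity
  (`U = ½ Σ|Tᵢ − 360/n|` over sorted arc gaps, Monte-Carlo p-values),
  Rao's homogeneity test across individuals, and UPGMA clustering of
  hourly detection profiles.
- **Binomial GAMs** (via `mgcv`, REML) for daily detection probability,
  the roaming index, and hourly detection probability: cyclic cubic
  smooths for month and hour, per-tag random intercepts, and candidate
  sets ranked by `AICc = AIC + 2k(k+1)/(n − k − 1)`.
- **Space use** by water-masked dynamic Brownian bridge movement models
  (dBBMM): tracks reconstructed from gate passages (5 min–24 h joining
  rule), windowed maximum-likelihood motion variance, Gaussian bridges
  integrated over a grid with bridges routed along the shortest in-water
  path where the straight chord crosses land, 50% highest-density
  contours, and directed percentage overlap between groups.
- A **synthetic tidal-inlet simulator** generating datasets with known
  seasonal occupancy, sex-specific departure dynamics, tide-driven male
  movement, and logistic distance-dependent detection — every latent
  parameter recorded, so each stage of the pipeline can be tested by
  parameter recovery.

## Worked example

Simulate six months of a nine-shark study on a five-gate array, curate it,
and compute the residency statistics:

```r
library(tidegate)

scenario <- sim_scenario(study_days = 180, n_females = 5, n_males = 4,
                         emission = c(300, 600))
sim <- simulate_telemetry(scenario, seed = 42)
#> Simulated telemetry: 35781 detections, 9 tags, 5 receivers, 180 days (seed 42)

cur <- curate_detections(sim$detections,
                         tagging_days = sim$config$study_start - 1:3)
cur$report
#> Detection curation report
#>   input detections:         35781
#>   collision-like removed:   34
#>   daily singletons removed: 268
#>   ...
#>   output detections:        35479

p <- build_presence(cur$detections, receivers = sim$receivers$receiver_id)
head(residency_indices(p)[c("tag_id", "days_detected", "min_residency",
                            "max_residency", "category")])
#>   tag_id days_detected min_residency max_residency   category
#> 1    T01           123     0.6833333     0.7235294  long-term
#> 2    T02           113     0.6277778     0.6277778  long-term
#> 6    T06            77     0.4277778     0.7264151 short-term
```

`T06` is a male: it departed abruptly around day 100–118 (the simulated
male exodus at the end of the high season), so its minimum residency —
which charges it for the rest of the study — drops to 0.43 while its
maximum residency stays high. Roaming indices (`roaming_index(p)`) run
0.61–0.88 here: every animal used most of the array on its present days.

Model the daily detection probability and rank candidates by AICc:

```r
amp <- daily_amplitude(sim$tide, sim$config)
tab <- build_seasonal_table(p, sim$tags, sim$sst, amp)
fits <- fit_candidates(tab, list(
  month_sex_tag = detected ~ sex + s(month, bs = "cc", k = 6) +
    s(month, by = sex, bs = "cc", k = 6) + s(tag, bs = "re"),
  month_tag = detected ~ sex + s(month, bs = "cc", k = 6) + s(tag, bs = "re"),
  month_only = detected ~ sex + s(month, bs = "cc", k = 6)))
fits$ranking
#>           model     k  aic aicc delta_aicc dev_expl converged
#> 1    month_only 5.134 1372 1372      0.000   0.1140      TRUE
#> 2 month_sex_tag 7.558 1375 1375      2.455   0.1156      TRUE
#> 3     month_tag 7.571 1375 1375      2.464   0.1156      TRUE
```

(On this short 180-day window the sex-by-month interaction is not worth
its parameters; on a full-length simulation it is — see the package
tests.) Finally, sex-specific space use and its overlap:

```r
tracks <- build_tracks(cur$detections, sim$receivers)
uds <- lapply(c(female = "female", male = "male"), function(sx) {
  ids <- sim$tags$tag_id[sim$tags$sex == sx]
  dbbmm_ud(tracks[tracks$tag_id %in% ids, ], water = sim$water, cell = 100)
})
ud_overlap(ud_contour(uds$female), ud_contour(uds$male))
#> a_in_b b_in_a
#>   22.5   27.6
```

The simulated males ride the flood tide into the upper inlet and drop
below the array on the ebb, so their 50% contour only partially overlaps
the females' — the kind of contrast the overlap statistic is built to
expose.

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/tidal-inlet-telemetry.Rmd`) describes the statistical
model choices, simulator assumptions, numerical tolerances and known
limitations in detail.
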
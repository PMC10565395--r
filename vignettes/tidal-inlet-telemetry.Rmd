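---
title: "Methods: gate-array telemetry analysis in a tidal inlet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gate-array telemetry analysis in a tidal inlet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tidegate` implements the analysis chain for passive acoustic telemetry
studies that monitor a mobile marine predator with a line of receiver
"gates" along a narrow tidal inlet. This vignette records the statistical
content of each stage: the model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Temporal conventions

All timestamps are stored in UTC; analyses that depend on a *day* or an
*hour of day* convert through a configurable local offset
(`study_config()`, default −3 h, appropriate for Patagonia). Daily
presence is sensitive to this convention — a detection at 23:59 local and
one at 00:01 local belong to different days — so the offset is an explicit
study parameter rather than an implementation detail.

The study duration is the *exclusive* day difference `study_end −
study_start`. This is the convention under which the canonical 1 November
2019 → 12 March 2021 window spans 497 days, and it is the denominator of
the minimum residency index. Day *spans* (first to last detection), by
contrast, count both endpoints, matching the everyday reading of "detected
from day X to day Y". The two conventions meet at one degenerate point: a
tag whose span covers the whole window has a 498-day span over a 497-day
study. We resolve it by capping the minimum index at the maximum, which
makes the bracket ordering `min ≤ max` exact, with equality precisely when
the detection span covers the study window.

## Curation

Receivers cannot log a true code collision, so collisions are
operationalized as groups of detections of *different* tags at the *same*
receiver within a short window (default 1 s, strict inequality; the window
is configurable). Every member of such a group is removed, as is any
repeated identical row. Daily singletons — a single detection of a tag at
a receiver within a local day — are the classic false-detection signature
and are removed next. The order matters and is fixed: collision removal
can orphan a second detection into a singleton, so it runs first; a
property test pins this order.

Two tag-level filters follow. Tags whose entire history falls within the
first days of the study (default horizon 5 days, measured from the study
start) are indistinguishable from early tag loss or tagging-induced
mortality and are excluded with a reason code. Tags detected day after day
at a single receiver over a long run (default span ≥ 30 days, allowing
1-day gaps) are *flagged* as probable shed transmitters but not removed
automatically — that judgement call (the flagged pattern can also be a
genuinely stationary animal) is left to inspection, with
`exclude_stationary = TRUE` available once made.

## Residency, roaming, and departure correction

The daily presence matrix (tags × days, with per-day receiver sets) is the
basis of everything. A tag is *present* on a day when it has at least one
post-curation detection; we considered requiring two, but curation already
removes daily singletons, so a surviving single-receiver day carries at
least two raw detections.

The two residency indices bracket truth from opposite sides: the maximum
(days detected / span) ignores possible absence after the last detection;
the minimum (days detected / study duration) charges the animal for every
undetected study day, including those after it may have permanently left.
Categories follow conventional thresholds on the minimum index: below 0.1
vagrant, 0.1–0.5 (inclusive) short-term, above 0.5 long-term resident.

The detected/remaining proportion corrects a naive abundance index for
permanent departures without modelling mortality: the denominator on day
*d* counts tags whose *final* detection is on or after *d*. A tag thus
leaves the population the day after its last detection — an assumption
that treats disappearance as departure, defensible when tag loss and
mortality are believed low, and stated rather than hidden. When the
denominator is empty the proportion is missing, never zero.

## Tide covariates

Hourly heights come from half-cosine interpolation between tabulated
high/low extremes — the standard approximation for a semidiurnal regime
when harmonic constituents are not available. A gap longer than 15 h
between extremes indicates a missing entry and is an error, not silently
interpolated. Height classes cut the full hourly series at its empirical
0.25/0.75 quantiles; the estimator is fixed to R's type-7
(linear-interpolation) quantile because the class boundaries depend on it.
When the two quantiles coincide (a degenerate constant series) the strict
comparisons leave everything `intermediate`. Direction is the sign of the
hourly height difference, with exact slack ties inheriting the previous
hour's label. Strength is `weak` only near slack water: within one hour of
an extreme *and* with the height still within 0.5 m (strict, configurable)
of that extreme's height — on a large spring tide the water may already
have moved further than that within the slack hour, which correctly
classifies as `strong`.

Calibration against in-situ logger records fits `logger ≈ offset + scale ·
predicted(t − lag)` by least squares over a ±120 min lag grid in 5-min
steps, reporting all three parameters plus RMSE; ties in RMSE resolve to
the smallest absolute lag. We fit the full affine-plus-lag model rather
than choosing among offset-only, regression-only or lag-only corrections,
because the three are nested within it and the fitted values report which
are active.

## Circular hour-of-day statistics

Detection instants map to angles at 15°/hour of fractional local time.
Rao's spacing statistic is `U = ½ Σ|Tᵢ − λ|` over the successive arc gaps
of the sorted sample (wrap-around gap included), `λ = 360/n`. P-values are
Monte-Carlo — the share of uniform samples of the same size with `U` at
least the observed — under a caller-supplied seed (default 10 000
replicates), rather than the coarse published critical-value tables; the
MC route gives exact-level, reproducible inference at any `n ≥ 4`.

Rao's homogeneity test compares polar vectors across individuals: for each
sample the mean direction and resultant length are estimated with
delta-method variances from the cosine/sine moments, and each component
yields a weighted chi-square on k−1 degrees of freedom; we also report
their sum on 2(k−1) d.f. Mean-direction angles are centred on their
circular mean before differencing so the wrap point sits opposite the
data. Samples with a null resultant (mean direction undefined) are an
error, not a silent zero.

Hourly profiles (per-tag proportions over the 24 integer local hours) are
clustered with average-linkage (UPGMA) hierarchical clustering under
Euclidean distance; the distance is a design choice — only the linkage is
canonical in this literature — and duplicates merge at height zero, ties
resolved by `hclust`'s deterministic ordering.

## Binomial additive models and AICc

Three model tables feed `mgcv::gam` (binomial family, REML):

* *Seasonal detection*: one row per tag-day from the study start through
  that tag's last detection, response 1/0 detected.
* *Roaming*: one row per present tag-day, response
  `cbind(visited, R − visited)` over the `R` active receivers, with the
  per-sex detected/remaining proportions (`prop_f`, `prop_m`) as
  covariates.
* *Intra-day detection*: 24 hourly rows per present tag-day, joined with
  the hourly tide covariates.

Month and hour get cyclic cubic smooths (`bs = "cc"`) with knots at
0.5/12.5 and −0.5/23.5 so predictions are periodic across the year and day
boundaries; a test asserts the boundary values agree. Temperature gets an
ordinary thin-plate basis by default — it is seasonal but not inherently
periodic, and forcing February and August to join would be a modelling
artefact; a cyclic basis remains available through the formula interface.
Random intercepts use the ridge-penalty device `s(tag, bs = "re")`; the
"tag within sex" variant uses the interaction factor, which for tags of a
single sex is a reparameterisation of the per-tag intercept and is kept
for the candidate-set structure. Rows with missing covariates are dropped
listwise with a count message (imputation is out of scope).

Candidate sets follow the usual nesting: a global model, drop-one-term
variants, and the three random-effect variants (tag, tag-within-sex,
none). Ranking uses `AICc = AIC + 2k(k+1)/(n − k − 1)` with `k` the fit's
total effective degrees of freedom (as reported through `logLik`), which
makes AICc values backend-sensitive; conclusions should rest on the
*ranking* and on effect recovery, not on absolute AICc values, and
non-converged fits are excluded from the ranking with a warning.

## Dynamic Brownian bridge space use

Tracks are rebuilt from gate passages: consecutive detections at different
receivers joined when separated by 5 min to 24 h; longer silences start a
new track; a receiver change faster than 5 min is unresolvable for a gate
array and also breaks the track; same-receiver runs collapse to their
first and last fixes, forming zero-displacement residence bridges.

The motion variance σ²ₘ (m²/s) is estimated per sliding window (default 31
fixes, margin 11) by maximizing the leave-one-out likelihood of the
window's odd interior fixes under the Brownian bridge with location error
δ; the window defaults are the conventional dBBMM choices. Optimization is
1-D on log₁₀σ²ₘ over [−8, 6] by golden-section search; a perfectly
interpolable (straight, constant-velocity) track correctly drives the
estimate to the lower bound. Tracks shorter than the window fall back to a
single track-wide estimate.

The UD integrates each bridge's Gaussian density over a regular grid
(midpoint rule in time, default 15 steps per bridge; the two spatial
dimensions share the variance, so the density evaluation is a separable
outer product truncated at 5σ). The bridge variance at interior time `t`
of span `T` is `t(T−t)/T·σ²ₘ + (1−t/T)²δ² + (t/T)²δ²`. For residence
bridges — both fixes at the *same* receiver — the two endpoint errors are
one and the same detection-range disc, not independent draws, so the error
term is a single `δ²`; this correlated-error treatment also makes the UD
of a stationary cluster exactly the circular Gaussian with variance δ²,
whose 50% highest-density region has the closed-form area `2π·ln2·δ²`
used as an analytic test. The location error defaults to δ = 200 m, half
the nominal effective detection range of the receivers this design
assumes (~400 m); the cell size defaults to 50 m, small against an inlet
a few hundred metres wide.

Where the straight chord between fixes crosses land, the bridge is routed
along the shortest in-water path on a visibility graph over the polygon
vertices, subdividing the bridge at the waypoints with time allocated by
path-length fraction. Chord-in-water testing combines proper-crossing
tests against every polygon edge with interior-point sampling; fixes that
fall outside the supplied polygon fall back to the straight chord rather
than failing. After accumulation the UD is masked to water and
renormalized to unit mass; contours take the highest-density cells until
the level is reached, ties broken by cell index for determinism, and the
directed overlap between two groups' contours is the shared area as a
percentage of each. Group UDs are obtained by pooling the group's tracks
into one call — bridges are duration-weighted, so this is a
tracked-time-weighted pooling.

## The synthetic-data generator

`sim_scenario()` encodes the study conditions the package assumes: a
15 km × 500 m inlet, five gates 2 km apart along its upper half, 11 + 7
tagged adults, daily presence following a raised-cosine seasonal occupancy
peaking in December (default 0.85 at peak, 0.10 in the trough), abrupt
male departure within an 18-day window at the end of the high season
against a gradual female daily hazard, Ornstein–Uhlenbeck along-inlet
movement (stationary SD 2.5 km, relaxation 2 h), an M2 semidiurnal tide
(12.42 h) with spring–neap modulation, transmissions at uniform 60–180 s
intervals, logistic distance detection (d₅₀ = 250 m, shape 50 m, i.e.
effective range ≈ 360 m) with mildly tide-modulated range, and an SST
cycle from 8 °C in August to 18 °C in February. Males ride the flood into
the upper inlet and drop below the array's coverage on the ebb — the
behavioural mechanism generating a male-only tide-height effect on
detection probability, mirroring the pattern this kind of analysis is
meant to detect. A single `sex_differences = FALSE` switch produces the
matched null scenario.

Movement is simulated exactly on a 5-min grid (the OU recursion is a
linear filter, evaluated in C via `stats::filter`), transmissions are
placed by accumulating uniform emission intervals and positions
interpolated onto them; detection is Bernoulli per transmission and
receiver. The generator reproduces the *statistical structure* the
analysis assumes — seasonal occupancy, departure dynamics, gate geometry,
distance-dependent detection — but deliberately not: hydrodynamics or
current-driven advection, prey fields, depth use, receiver outages, or
clock drift. Passing recovery tests therefore demonstrates that the
pipeline recovers truth *under its own assumptions*, not that those
assumptions hold in any particular field system.

Test problem sizes are chosen to exercise every code path while keeping
the suite quick: the shared fixture simulates 7 tags over 120 days with
slowed transmitters; the parameter-recovery checks use the full 18-tag
configuration over one simulated year, where the fitted cyclic month
smooth peaks within a month of the December truth, the month-by-sex smooth
is significant under sex-specific departures and not under the null, and
the male high-minus-low tide contrast is positive.

## Known limitations

* Positions exist only at receiver resolution; the dBBMM inherits that
  granularity, and within-gate movement is invisible.
* The detected/remaining correction conflates death, tag loss and
  permanent emigration; all are "departure".
* The homogeneity test's delta-method variances need non-degenerate
  within-sample spread; point-mass samples are rejected.
* AICc uses effective degrees of freedom from a penalized fit; model
  ranks are stable across backends in our tests, absolute values are not.
* The visibility-graph routing assumes a single simple polygon (no
  islands); multi-part water bodies would need a constrained
  triangulation, which is out of scope.
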
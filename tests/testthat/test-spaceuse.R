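rec5 <- data.frame(receiver_id = paste0("R", 1:5),
                   x = seq(6500, 14500, by = 2000), y = 250,
                   stringsAsFactors = FALSE)

test_that("track building follows the gap rules", {
  cfg <- hist_cfg()
  t0 <- as.POSIXct("2020-01-10 10:00:00", tz = "UTC")
  # R1 then R2 one hour later: one joined segment
  d <- detection_table(c(t0, t0 + 3600), "A", c("R1", "R2"), cfg)
  tr <- build_tracks(d, rec5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 2)
  # receiver change after only 2 min: below the 5-min floor, not joined
  d2 <- detection_table(c(t0, t0 + 120), "A", c("R1", "R2"), cfg)
  expect_equal(nrow(build_tracks(d2, rec5)), 0)
  # a 30 h silence starts a new track
  d3 <- detection_table(c(t0, t0 + 3600, t0 + 3600 + 30 * 3600,
                          t0 + 2 * 3600 + 30 * 3600),
                        "A", c("R1", "R2", "R2", "R3"), cfg)
  tr3 <- build_tracks(d3, rec5)
  expect_equal(length(unique(tr3$track_id)), 2)
  # same-receiver runs collapse to their first and last fixes
  d4 <- detection_table(t0 + c(0, 600, 1200, 1800, 4000), "A",
                        c(rep("R1", 4), "R2"), cfg)
  tr4 <- build_tracks(d4, rec5)
  expect_equal(nrow(tr4), 3)
  expect_equal(tr4$receiver_id, c("R1", "R1", "R2"))
  expect_equal(tr4$time[1:2], as.numeric(t0) + c(0, 1800))
})

test_that("motion variance vanishes for deterministic geometry", {
  # straight constant-velocity track observed without noise
  n <- 41
  tr <- data.frame(tag_id = "a", track_id = 1L,
                   time = seq(0, by = 600, length.out = n),
                   x = seq(0, by = 100, length.out = n), y = 0,
                   receiver_id = "r")
  mv <- motion_variance(tr, window = 31, margin = 11, delta = 50)
  expect_lt(max(mv$sigma2m), 1e-6)
  # short track falls back to a single track-wide estimate
  short <- tr[1:5, ]
  mv2 <- motion_variance(short, window = 31, margin = 11, delta = 50)
  expect_equal(length(unique(mv2$sigma2m)), 1)
})

test_that("motion variance recovers a known Brownian diffusion", {
  set.seed(4)
  s2_true <- 4   # m^2/s
  n <- 200; dt <- 60
  est <- vapply(1:3, function(rep) {
    x <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(s2_true * dt))))
    y <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(s2_true * dt))))
    tr <- data.frame(tag_id = "a", track_id = rep, time = (0:(n - 1)) * dt,
                     x = x, y = y, receiver_id = "r")
    stats::median(motion_variance(tr, delta = 1)$sigma2m)
  }, numeric(1))
  expect_lt(abs(mean(est) - s2_true) / s2_true, 0.2)
})

test_that("the UD conserves mass, masks land and refines stably", {
  set.seed(6)
  n <- 30
  tr <- data.frame(tag_id = "a", track_id = 1L,
                   time = seq(0, by = 1800, length.out = n),
                   x = cumsum(c(500, stats::rnorm(n - 1, 40, 120))),
                   y = 250 + stats::rnorm(n, 0, 60),
                   receiver_id = "r")
  tr$y <- pmin(pmax(tr$y, 30), 470)
  water <- water_polygon(rbind(c(-500, 0), c(6000, 0), c(6000, 500),
                               c(-500, 500)))
  tr$x <- pmin(pmax(tr$x, 0), 5500)
  ud <- dbbmm_ud(tr, water = water, cell = 50, delta = 100)
  expect_equal(sum(ud$p), 1, tolerance = 1e-9)
  expect_true(all(ud$p[!ud$water] == 0))
  # a mask cropping the distribution still renormalizes to 1
  half <- water_polygon(rbind(c(-500, 0), c(6000, 0), c(6000, 250),
                              c(-500, 250)))
  ud2 <- dbbmm_ud(tr, water = half, cell = 50, delta = 100)
  expect_equal(sum(ud2$p), 1, tolerance = 1e-9)
  # contour areas are monotone in the level
  a25 <- ud_contour(ud, 0.25)$area
  a50 <- ud_contour(ud, 0.5)$area
  a95 <- ud_contour(ud, 0.95)$area
  expect_lte(a25, a50); expect_lte(a50, a95)
  # grid refinement changes the 50% area by less than 5%
  ud_f <- dbbmm_ud(tr, water = water, cell = 25, delta = 100)
  expect_lt(abs(ud_contour(ud_f, 0.5)$area - a50) / a50, 0.05)
})

test_that("a single open-water bridge matches fine-grid quadrature", {
  # oracle: independent direct integration of the bridge density over a
  # dense time grid at each cell centre
  delta <- 80; s2 <- 2; Tt <- 3600
  a <- c(0, 0); b <- c(800, 300)
  tr <- data.frame(tag_id = "a", track_id = 1L, time = c(0, Tt),
                   x = c(a[1], b[1]), y = c(a[2], b[2]), receiver_id = "r")
  tr$sigma2m <- s2
  ud <- dbbmm_ud(tr, water = NULL, cell = 40, delta = delta, n_steps = 200)
  oracle <- matrix(0, length(ud$x), length(ud$y))
  tg <- (seq_len(2000) - 0.5) / 2000 * Tt
  u <- tg / Tt
  vv <- tg * (Tt - tg) / Tt * s2 + ((1 - u)^2 + u^2) * delta^2
  for (q in seq_along(tg)) {
    oracle <- oracle + stats::dnorm(ud$x, a[1] + u[q] * (b[1] - a[1]),
                                    sqrt(vv[q])) %o%
      stats::dnorm(ud$y, a[2] + u[q] * (b[2] - a[2]), sqrt(vv[q]))
  }
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(oracle - ud$p)), 1e-4)
  expect_gt(stats::cor(as.vector(oracle), as.vector(ud$p)), 0.999)
})

test_that("contours and overlaps have their exact small-case values", {
  grid <- list(x = seq_len(10), y = seq_len(10), cell = 1,
               water = matrix(TRUE, 10, 10))
  uniform <- structure(c(grid, list(p = matrix(0.01, 10, 10))),
                       class = "tg_ud")
  expect_equal(ud_contour(uniform, 0.5)$area, 50)
  expect_equal(ud_contour(uniform, 1)$area, 100)
  point <- structure(c(grid, list(p = {
    m <- matrix(0, 10, 10); m[5, 5] <- 1; m
  })), class = "tg_ud")
  expect_equal(ud_contour(point, 0.5)$area, 1)
  # overlaps: identical, disjoint, nested 1:2
  ct <- function(cells) structure(list(level = 0.5, area = length(cells),
                                       cells = cells, mass = 0.5,
                                       dim = c(10L, 10L), cell = 1),
                                  class = "tg_contour")
  expect_equal(unname(ud_overlap(ct(1:10), ct(1:10))), c(100, 100))
  expect_equal(unname(ud_overlap(ct(1:10), ct(21:30))), c(0, 0))
  expect_equal(unname(ud_overlap(ct(1:10), ct(1:20))), c(100, 50))
})

test_that("bridges route around land through the in-water path", {
  # U-shaped water body: the straight chord between the arms crosses land
  u_poly <- water_polygon(rbind(
    c(0, 0), c(300, 0), c(300, 260), c(200, 260), c(200, 60),
    c(100, 60), c(100, 260), c(0, 260)))
  a <- c(50, 200); b <- c(250, 200)
  expect_false(tidegate:::chord_in_water(a, b, u_poly))
  path <- in_water_path(a, b, u_poly)
  expect_gt(nrow(path), 2)
  # path length exceeds the chord and every waypoint is in water
  seglen <- sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                              path[-nrow(path), , drop = FALSE])^2)))
  expect_gt(seglen, sqrt(sum((a - b)^2)))
  expect_true(all(point_in_polygon(path[, 1], path[, 2], u_poly)))
  # the UD of that bridge keeps its mass inside the water mask
  tr <- data.frame(tag_id = "a", track_id = 1L, time = c(0, 1800),
                   x = c(a[1], b[1]), y = c(a[2], b[2]), receiver_id = "r")
  tr$sigma2m <- 0.5
  ud <- dbbmm_ud(tr, water = u_poly, cell = 10, delta = 15, pad = 50)
  expect_equal(sum(ud$p), 1, tolerance = 1e-9)
  expect_true(all(ud$p[!ud$water] == 0))
  # mass concentrates in the connecting corridor (lower arm), not on land
  corridor <- ud$x > 100 & ud$x < 200
  low <- ud$y < 60
  expect_gt(sum(ud$p[corridor, low]), 0.05)
})

test_that("the ASCII grid export round-trips the UD values", {
  tr <- data.frame(tag_id = "a", track_id = 1L, time = c(0, 1800),
                   x = c(0, 400), y = c(0, 0), receiver_id = "r")
  tr$sigma2m <- 1
  ud <- dbbmm_ud(tr, water = NULL, cell = 50, delta = 100)
  f <- tempfile(fileext = ".asc")
  write_ud_asc(ud, f)
  lines <- readLines(f)
  expect_equal(lines[1], sprintf("ncols %d", length(ud$x)))
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = length(ud$y), byrow = TRUE)
  # first data row is the northernmost y
  expect_equal(m[1, ], ud$p[, length(ud$y)], tolerance = 1e-6)
  expect_equal(sum(m), 1, tolerance = 1e-4)
})
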
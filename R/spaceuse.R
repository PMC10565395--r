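#' Reconstruct movement tracks from gate detections
#'
#' Turns the detection sequence of each tag into time-ordered position fixes
#' at the receiver coordinates. Consecutive detections are joined into a
#' track segment when they occur at *different* receivers separated by at
#' least `min_gap` and at most `max_gap`; a silence longer than `max_gap`
#' starts a new track, and a receiver change faster than `min_gap` also
#' breaks the track (a gate array cannot resolve such movement). Runs of
#' detections at the same receiver are collapsed to their first and last
#' fixes (a residence bridge of zero displacement).
#'
#' @param det A curated [detection_table()].
#' @param receivers Receiver metadata with `receiver_id`, `x`, `y`.
#' @param min_gap,max_gap Seconds (defaults 5 min and 24 h).
#' @return `data.frame` of class `tg_tracks`: `tag_id`, `track_id`, `time`,
#'   `x`, `y`, `receiver_id`.
#' @export
build_tracks <- function(det, receivers, min_gap = 300, max_gap = 86400) {
  m <- match(det$receiver_id, receivers$receiver_id)
  if (anyNA(m)) stop("detections reference receivers missing from metadata")
  fixes <- data.frame(tag_id = det$tag_id,
                      time = as.numeric(det$timestamp),
                      x = receivers$x[m], y = receivers$y[m],
                      receiver_id = det$receiver_id,
                      stringsAsFactors = FALSE)
  out <- list(); trk <- 0L
  for (tg in unique(fixes$tag_id)) {
    f <- fixes[fixes$tag_id == tg, , drop = FALSE]
    f <- f[order(f$time), , drop = FALSE]
    n <- nrow(f)
    dt <- diff(f$time)
    same <- f$receiver_id[-1] == f$receiver_id[-n]
    # break before fix i+1 when silence too long, or receiver changed too fast
    brk <- (dt > max_gap) | (!same & dt < min_gap)
    seg <- cumsum(c(0, brk))
    for (s in unique(seg)) {
      g <- f[seg == s, , drop = FALSE]
      # collapse same-receiver runs to first/last fix
      r <- rle(g$receiver_id)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      keep <- sort(unique(c(starts, ends)))
      g <- g[keep, , drop = FALSE]
      if (nrow(g) < 2) next
      trk <- trk + 1L
      g$track_id <- trk
      out[[length(out) + 1]] <- g
    }
  }
  tr <- do.call(rbind, out)
  if (is.null(tr))
    tr <- data.frame(tag_id = character(), time = numeric(), x = numeric(),
                     y = numeric(), receiver_id = character(),
                     track_id = integer())
  tr <- tr[c("tag_id", "track_id", "time", "x", "y", "receiver_id")]
  rownames(tr) <- NULL
  class(tr) <- c("tg_tracks", "data.frame")
  tr
}

# Negative log-likelihood of the leave-one-out interior fixes of one window
# given a motion variance (m^2/s). Every odd interior fix is predicted from
# its two neighbours under the Brownian bridge with location error delta.
bridge_nll <- function(sigma2, tt, xx, yy, delta) {
  idx <- seq(2, length(tt) - 1, by = 2)
  if (!length(idx)) return(NA_real_)
  a <- idx - 1; b <- idx + 1
  Tt <- tt[b] - tt[a]
  al <- (tt[idx] - tt[a]) / Tt
  v <- Tt * al * (1 - al) * sigma2 +
    (1 - al)^2 * delta^2 + al^2 * delta^2 + delta^2
  mx <- xx[a] + al * (xx[b] - xx[a])
  my <- yy[a] + al * (yy[b] - yy[a])
  -sum(stats::dnorm(xx[idx], mx, sqrt(v), log = TRUE) +
       stats::dnorm(yy[idx], my, sqrt(v), log = TRUE))
}

#' Dynamic motion variance along tracks
#'
#' The dynamic Brownian bridge motion variance: within a sliding window of
#' fixes, the Brownian motion variance (m^2/s) is estimated by maximizing
#' the leave-one-out likelihood of the window's interior fixes, and the
#' estimate is assigned to the window's central fix (edge fixes inherit the
#' nearest estimate). Tracks shorter than the window fall back to a single
#' track-wide estimate.
#'
#' @param tracks A [build_tracks()] table.
#' @param window Window length in fixes (odd; default 31).
#' @param margin Minimum fixes on each side of the focal fix (default 11);
#'   retained for interface compatibility, the window bound is what is
#'   enforced.
#' @param delta Location error (m), the scale of a receiver's detection
#'   range.
#' @return `tracks` with a `sigma2m` column (m^2/s) added.
#' @export
motion_variance <- function(tracks, window = 31, margin = 11, delta = 200) {
  if (window %% 2 == 0) window <- window + 1
  if (window < 2 * margin + 1) stop("window must be at least 2*margin + 1")
  est <- function(tt, xx, yy) {
    if (length(tt) < 3) return(1e-8)
    o <- stats::optimize(function(ls) bridge_nll(10^ls, tt, xx, yy, delta),
                         interval = c(-8, 6))
    10^o$minimum
  }
  tracks$sigma2m <- NA_real_
  for (id in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == id)
    tt <- tracks$time[sel]; xx <- tracks$x[sel]; yy <- tracks$y[sel]
    n <- length(sel)
    s2 <- numeric(n)
    if (n < window) {
      s2[] <- est(tt, xx, yy)
    } else {
      half <- (window - 1) / 2
      centers <- (half + 1):(n - half)
      vals <- vapply(centers, function(c0) {
        w <- (c0 - half):(c0 + half)
        est(tt[w], xx[w], yy[w])
      }, numeric(1))
      s2[centers] <- vals
      s2[seq_len(half)] <- vals[1]
      s2[(n - half + 1):n] <- vals[length(vals)]
    }
    tracks$sigma2m[sel] <- s2
  }
  tracks
}

#' Water-masked dynamic Brownian bridge utilization distribution
#'
#' Integrates Gaussian Brownian bridges between consecutive fixes of each
#' track over a regular grid, weighting each bridge by its duration, then
#' masks land and renormalizes so the UD sums to 1 over water. At interior
#' time `t` of a bridge from `a` (time 0) to `b` (time `T`) the density is
#' circular Gaussian with mean on the chord and variance
#' `t(T-t)/T * sigma2m + (1-t/T)^2 delta^2 + (t/T)^2 delta^2`. When the two
#' fixes are the *same* position (a residence bridge at one receiver) the
#' endpoint errors are one and the same detection-range disc, so the error
#' term is a single `delta^2` rather than the two-endpoint split. Bridges
#' whose straight chord crosses land are routed along the shortest in-water
#' path ([in_water_path()]) and subdivided at the waypoints, allocating time
#' by path-length fraction.
#'
#' Pooling several individuals' tracks (e.g. one sex) into one call yields
#' the group UD, weighted by tracked time.
#'
#' @param tracks A [build_tracks()] table; `sigma2m` is computed via
#'   [motion_variance()] if absent.
#' @param water Optional [water_polygon()]; when `NULL` no mask is applied
#'   and the grid covers the fixes' bounding box.
#' @param cell Grid cell size (m), default 50.
#' @param delta Location error (m), default 200 (half a receiver's
#'   effective range).
#' @param window,margin Passed to [motion_variance()] when needed.
#' @param n_steps Time-integration steps per bridge (midpoint rule,
#'   default 15).
#' @param pad Grid padding beyond the bounding box (m), default `4 * delta`.
#' @return A `tg_ud`: list with `p` (probability matrix, rows = x cells,
#'   cols = y cells, summing to 1 over water), `x`, `y` (cell centers),
#'   `cell`, `water` (logical mask).
#' @export
dbbmm_ud <- function(tracks, water = NULL, cell = 50, delta = 200,
                     window = 31, margin = 11, n_steps = 15, pad = NULL) {
  if (!nrow(tracks)) stop("empty track table")
  if (is.null(tracks$sigma2m))
    tracks <- motion_variance(tracks, window, margin, delta)
  if (is.null(pad)) pad <- 4 * delta
  bbox <- c(min(tracks$x), max(tracks$x), min(tracks$y), max(tracks$y))
  grid <- if (is.null(water)) {
    make_grid(poly = NULL, cell = cell, bbox = bbox, pad = pad)
  } else {
    make_grid(poly = water, cell = cell,
              bbox = c(min(bbox[1], min(water[, 1])), max(bbox[2], max(water[, 1])),
                       min(bbox[3], min(water[, 2])), max(bbox[4], max(water[, 2]))),
              pad = pad)
  }
  dens <- matrix(0, length(grid$x), length(grid$y))
  total_w <- 0
  for (id in unique(tracks$track_id)) {
    f <- tracks[tracks$track_id == id, , drop = FALSE]
    n <- nrow(f)
    for (i in seq_len(n - 1)) {
      a <- c(f$x[i], f$y[i]); b <- c(f$x[i + 1], f$y[i + 1])
      Tt <- f$time[i + 1] - f$time[i]
      if (Tt <= 0) next
      s2 <- mean(c(f$sigma2m[i], f$sigma2m[i + 1]), na.rm = TRUE)
      same_pos <- all(a == b)
      route <- !is.null(water) && !same_pos &&
        all(point_in_polygon(c(a[1], b[1]), c(a[2], b[2]), water))
      way <- if (route) in_water_path(a, b, water) else rbind(a, b)
      seg_len <- sqrt(rowSums((way[-1, , drop = FALSE] -
                               way[-nrow(way), , drop = FALSE])^2))
      frac <- if (sum(seg_len) > 0) seg_len / sum(seg_len) else
        rep(1 / length(seg_len), length(seg_len))
      t_bounds <- c(0, cumsum(frac)) * Tt
      for (s in seq_len(nrow(way) - 1)) {
        a_s <- way[s, ]; b_s <- way[s + 1, ]
        T_s <- t_bounds[s + 1] - t_bounds[s]
        if (T_s <= 0) next
        u <- (seq_len(n_steps) - 0.5) / n_steps
        # global bridge time of each step (for the error split)
        tg <- t_bounds[s] + u * T_s
        ug <- tg / Tt
        vv <- tg * (Tt - tg) / Tt * s2 +
          if (same_pos) delta^2 else (1 - ug)^2 * delta^2 + ug^2 * delta^2
        mx <- a_s[1] + u * (b_s[1] - a_s[1])
        my <- a_s[2] + u * (b_s[2] - a_s[2])
        wstep <- T_s / n_steps
        for (q in seq_len(n_steps)) {
          sd <- sqrt(vv[q])
          ix <- which(abs(grid$x - mx[q]) < 5 * sd)
          iy <- which(abs(grid$y - my[q]) < 5 * sd)
          if (!length(ix) || !length(iy)) next
          dens[ix, iy] <- dens[ix, iy] + wstep *
            (stats::dnorm(grid$x[ix], mx[q], sd) %o%
             stats::dnorm(grid$y[iy], my[q], sd))
        }
        total_w <- total_w + T_s
      }
    }
  }
  if (total_w <= 0) stop("no usable bridges (all gaps non-positive)")
  dens[!grid$water] <- 0
  s <- sum(dens)
  if (s <= 0) stop("utilization distribution has no mass on water")
  structure(list(p = dens / s, x = grid$x, y = grid$y, cell = grid$cell,
                 water = grid$water), class = "tg_ud")
}

#' @export
print.tg_ud <- function(x, ...) {
  cat(sprintf("Utilization distribution: %d x %d cells of %g m (%d water)\n",
              length(x$x), length(x$y), x$cell, sum(x$water)))
  cat(sprintf("  mass on water: %.6f\n", sum(x$p)))
  invisible(x)
}

#' Highest-density UD contour
#'
#' The smallest set of highest-probability cells whose cumulative mass
#' reaches `level` (ties broken by cell index for determinism).
#'
#' @param ud A [dbbmm_ud()] result.
#' @param level Probability level, default 0.5.
#' @return A `tg_contour`: list with `level`, `area` (m^2), `cells`
#'   (linear indices into the UD matrix), `mass`.
#' @export
ud_contour <- function(ud, level = 0.5) {
  stopifnot(level > 0, level <= 1)
  p <- as.vector(ud$p)
  o <- order(-p, seq_along(p))
  cs <- cumsum(p[o])
  m <- which(cs >= level - 1e-12)[1]
  if (is.na(m)) m <- sum(p > 0)
  cells <- o[seq_len(m)]
  cells <- cells[p[cells] > 0]
  structure(list(level = level, area = length(cells) * ud$cell^2,
                 cells = cells, mass = sum(p[cells]),
                 dim = dim(ud$p), cell = ud$cell),
            class = "tg_contour")
}

#' @export
print.tg_contour <- function(x, ...) {
  cat(sprintf("%.0f%% UD contour: %d cells, area %.4g m^2 (mass %.3f)\n",
              100 * x$level, length(x$cells), x$area, x$mass))
  invisible(x)
}

#' Directed overlap between two UD contours
#'
#' `overlap(a|b) = area(a intersect b) / area(a) * 100`, asymmetric by
#' construction. The two contours must come from UDs on the same grid.
#'
#' @param a,b [ud_contour()] results on a common grid.
#' @return Named numeric vector `c(a_in_b = ..., b_in_a = ...)`, percent.
#' @export
ud_overlap <- function(a, b) {
  if (!identical(a$dim, b$dim) || !identical(a$cell, b$cell))
    stop("contours are not on the same grid")
  inter <- length(intersect(a$cells, b$cells))
  c(a_in_b = 100 * inter / length(a$cells),
    b_in_a = 100 * inter / length(b$cells))
}

#' Export a UD as an ESRI ASCII grid
#'
#' Plain-text raster export readable by standard GIS tools.
#'
#' @param ud A [dbbmm_ud()] result.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(ud, path) {
  nx <- length(ud$x); ny <- length(ud$y)
  hdr <- c(sprintf("ncols %d", nx),
           sprintf("nrows %d", ny),
           sprintf("xllcorner %.6f", ud$x[1] - ud$cell / 2),
           sprintf("yllcorner %.6f", ud$y[1] - ud$cell / 2),
           sprintf("cellsize %.6f", ud$cell),
           "NODATA_value -9999")
  rows <- vapply(rev(seq_len(ny)), function(j)
    paste(format(ud$p[, j], scientific = TRUE, digits = 7), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
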
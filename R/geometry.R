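# Planar geometry on the water polygon. Deliberately dependency-free: the
# inlet polygons this package handles are small (tens to hundreds of
# vertices), so O(n^2) segment tests are fine.

#' Point-in-polygon test
#'
#' Vectorized even-odd (ray casting) test. Points exactly on an edge are
#' treated as inside.
#'
#' @param px,py Coordinates of the query points.
#' @param poly A [water_polygon()] or two-column vertex matrix (open ring).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # collinear and within bounding box => on the edge
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    onseg <- abs(cross) < 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | onseg
  }
  inside | on_edge
}

# Orientation of triplet (sign of cross product).
orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sign(v) * (abs(v) > 1e-12)
}

# Proper intersection of open segments (a1,a2) and (b1,b2); touching at a
# shared endpoint does not count.
segments_cross <- function(a1, a2, b1, b2) {
  d1 <- orient(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- orient(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- orient(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- orient(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(ring) {
  n <- nrow(ring)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    for (k in (i + 1):n) {
      # skip adjacent edges (they share a vertex)
      if (k == i || nxt[k] == i || nxt[i] == k) next
      if (segments_cross(ring[i, ], ring[nxt[i], ],
                         ring[k, ], ring[nxt[k], ])) return(TRUE)
    }
  }
  FALSE
}

# Is the chord a->b entirely in water? Checks proper crossings against every
# polygon edge plus interior sampling (guards concave pockets whose boundary
# is only touched).
chord_in_water <- function(a, b, poly, n_check = 12) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  for (i in seq_len(n)) {
    if (segments_cross(a, b, poly[i, ], poly[nxt[i], ])) return(FALSE)
  }
  tt <- seq(0, 1, length.out = n_check)
  px <- a[1] + tt * (b[1] - a[1])
  py <- a[2] + tt * (b[2] - a[2])
  all(point_in_polygon(px, py, poly))
}

#' Shortest in-water path between two points
#'
#' Builds a visibility graph over the polygon vertices plus the two
#' endpoints (edges wherever the connecting chord stays in water) and
#' returns the shortest path through it.
#'
#' @param a,b Numeric length-2 points (must lie in water).
#' @param poly A [water_polygon()].
#' @return Matrix of waypoints from `a` to `b` (including both).
#' @export
in_water_path <- function(a, b, poly) {
  if (chord_in_water(a, b, poly)) return(rbind(a, b))
  pts <- rbind(a, b, unclass(poly)[, 1:2])
  m <- nrow(pts)
  edges <- NULL; weights <- NULL
  for (i in seq_len(m - 1)) {
    for (k in (i + 1):m) {
      if (chord_in_water(pts[i, ], pts[k, ], poly)) {
        edges <- c(edges, i, k)
        weights <- c(weights, sqrt(sum((pts[i, ] - pts[k, ])^2)))
      }
    }
  }
  if (is.null(edges)) stop("no in-water path between the points")
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  sp <- igraph::shortest_paths(g, from = 1, to = 2, weights = weights)
  vp <- as.integer(sp$vpath[[1]])
  if (!length(vp)) stop("no in-water path between the points")
  out <- pts[vp, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

# Regular grid of cell centers covering the polygon bounding box (+pad).
make_grid <- function(poly = NULL, cell, bbox = NULL, pad = 0) {
  if (is.null(bbox)) {
    if (is.null(poly)) stop("either poly or bbox is required")
    bbox <- c(min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2]))
  }
  x0 <- bbox[1] - pad; x1 <- bbox[2] + pad
  y0 <- bbox[3] - pad; y1 <- bbox[4] + pad
  xc <- seq(x0 + cell / 2, x1, by = cell)
  yc <- seq(y0 + cell / 2, y1, by = cell)
  water <- if (is.null(poly)) {
    matrix(TRUE, length(xc), length(yc))
  } else {
    outer(seq_along(xc), seq_along(yc), function(i, j)
      point_in_polygon(xc[i], yc[j], poly))
  }
  list(x = xc, y = yc, cell = cell, water = water)
}
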
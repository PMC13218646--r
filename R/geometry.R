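# Low-level planar geometry on bare coordinate lists.
#
# Conventions used throughout the package:
#   * a "line" is a numeric matrix with columns x, y (>= 2 rows);
#   * a "ring list" is a list of list(x = , y = ) rings in polyclip's format,
#     outer rings counter-clockwise (positive signed area), holes clockwise
#     (negative signed area), so the area of the region is the sum of signed
#     ring areas.
# All coordinates are planar metres in a projected CRS.

# Signed (shoelace) area of one ring.
ring_signed_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Area of a region represented as a ring list (holes negative).
rings_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, ring_signed_area, numeric(1)))
}

# Arc length of a polyline matrix.
polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# Cumulative arc length at each vertex (starts at 0).
polyline_cumlen <- function(coords) {
  c(0, cumsum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)))
}

# Point at arc length s along a polyline (s clamped to [0, length]).
polyline_point_at <- function(coords, s) {
  cl <- polyline_cumlen(coords)
  total <- cl[length(cl)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(i, nrow(coords) - 1L)
  seg <- cl[i + 1L] - cl[i]
  t <- if (seg > 0) (s - cl[i]) / seg else 0
  coords[i, ] + t * (coords[i + 1L, ] - coords[i, ])
}

# Sub-polyline between arc lengths s0 <= s1 (linear referencing, never chords).
polyline_substring <- function(coords, s0, s1) {
  cl <- polyline_cumlen(coords)
  total <- cl[length(cl)]
  s0 <- min(max(s0, 0), total)
  s1 <- min(max(s1, 0), total)
  if (s1 <= s0) return(NULL)
  keep <- which(cl > s0 & cl < s1)
  pts <- rbind(
    polyline_point_at(coords, s0),
    coords[keep, , drop = FALSE],
    polyline_point_at(coords, s1)
  )
  # drop consecutive duplicates introduced when s0/s1 fall on vertices
  d <- c(TRUE, rowSums(abs(diff(pts)))  > 1e-12)
  pts[d, , drop = FALSE]
}

# Projection of point p onto segment a-b: returns list(t, dist, point) where t
# is the position parameter in [0, 1] along the segment.
project_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 > 0) sum((p - a) * ab) / len2 else 0
  t <- min(max(t, 0), 1)
  q <- a + t * ab
  list(t = t, dist = sqrt(sum((p - q)^2)), point = q)
}

# Nearest point on a polyline: list(offset, dist, point); offset is arc length
# from the first vertex.
project_on_polyline <- function(coords, p) {
  cl <- polyline_cumlen(coords)
  best <- list(offset = 0, dist = Inf, point = coords[1, ])
  for (i in seq_len(nrow(coords) - 1L)) {
    pr <- project_on_segment(p, coords[i, ], coords[i + 1L, ])
    if (pr$dist < best$dist) {
      best <- list(
        offset = cl[i] + pr$t * (cl[i + 1L] - cl[i]),
        dist = pr$dist,
        point = pr$point
      )
    }
  }
  best
}

# Minimum distance from point p to a polyline.
dist_to_polyline <- function(coords, p) project_on_polyline(coords, p)$dist

# Even-odd point-in-polygon for a region given as a ring list; points on the
# boundary (within eps) count as inside.
point_in_rings <- function(rings, px, py, eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  on_boundary <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring$x
    y <- ring$y
    n <- length(x)
    j <- n
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- x[j]; yj <- y[j]
      # boundary proximity
      dx <- xj - xi; dy <- yj - yi
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- pmin(pmax(((px - xi) * dx + (py - yi) * dy) / len2, 0), 1)
        dd <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
        on_boundary <- on_boundary | dd <= eps^2
      } else {
        on_boundary <- on_boundary | ((px - xi)^2 + (py - yi)^2) <= eps^2
      }
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- k
    }
  }
  inside | on_boundary
}

# Ring list for an axis-aligned rectangle (counter-clockwise).
rect_ring <- function(xmin, ymin, xmax, ymax) {
  list(list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax)))
}

# Bounding box of a ring list: c(xmin, ymin, xmax, ymax).
rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  c(min(xs), min(ys), max(xs), max(ys))
}

# Intersection area of two regions (ring lists) via polyclip.
rings_intersection <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

# Heuristic guard: coordinates that all fit in lon/lat bounds are almost
# certainly geographic; metric computations would be silently wrong.
assert_projected <- function(x, y, what = "input") {
  if (length(x) == 0L) return(invisible(TRUE))
  if (all(abs(x) <= 180, na.rm = TRUE) && all(abs(y) <= 90, na.rm = TRUE)) {
    stop("projected metric CRS required: ", what,
         " coordinates look geographic (lon/lat)", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite coordinates in ", what, call. = FALSE)
  }
  invisible(TRUE)
}
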
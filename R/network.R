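#' Build a planar street network from polylines
#'
#' Welds polyline endpoints that lie within `weld_tolerance` of one another
#' into shared nodes and returns an undirected planar graph. The network is
#' the substrate for origin snapping, network-distance reachability, sausage
#' buffers and intersection counting.
#'
#' @param lines A list of polyline coordinate matrices (columns x, y, in
#'   metres of a projected CRS), or a single matrix.
#' @param weld_tolerance Endpoints closer than this (metres) are merged into
#'   one node. Default 0.01 m.
#' @param crs Optional label of the projected CRS the coordinates are in
#'   (e.g. an EPSG string); carried along and checked when geometries from
#'   different sources are combined.
#' @return A `street_network` object: a list with
#'   * `nodes`: tibble (`node_id`, `x`, `y`, `degree`),
#'   * `edges`: tibble (`edge_id`, `from`, `to`, `length`, `geometry`
#'     list-column of coordinate matrices).
#' @examples
#' net <- build_network(list(
#'   rbind(c(0, 0), c(100, 0)),
#'   rbind(c(100, 0), c(100, 100))
#' ))
#' net$nodes
#' @export
build_network <- function(lines, weld_tolerance = 0.01, crs = NULL) {
  if (is.matrix(lines)) lines <- list(lines)
  if (length(lines) == 0L) stop("empty network", call. = FALSE)
  lines <- lapply(lines, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 2L) {
      stop("each polyline needs >= 2 rows of (x, y) coordinates", call. = FALSE)
    }
    if (any(!is.finite(m))) stop("non-finite coordinates in network polylines",
                                 call. = FALSE)
    unname(m)
  })

  # Weld endpoints: single-linkage clustering of the 2 * n_lines endpoints,
  # pairs within tolerance found by hashing onto a grid of cell size = tol.
  ends <- do.call(rbind, lapply(lines, function(m) m[c(1L, nrow(m)), ]))
  node_of <- weld_points(ends, weld_tolerance)
  n_pts <- nrow(ends)
  node_ids <- node_of$id           # cluster id per endpoint
  node_xy <- node_of$xy            # representative coordinate per cluster

  from <- node_ids[seq(1L, 2L * length(lines), by = 2L)]
  to <- node_ids[seq(2L, 2L * length(lines), by = 2L)]

  # Snap polyline endpoints onto the welded node coordinate so that node
  # coordinates and edge geometry agree exactly.
  lines <- lapply(seq_along(lines), function(i) {
    m <- lines[[i]]
    m[1L, ] <- node_xy[from[i], ]
    m[nrow(m), ] <- node_xy[to[i], ]
    m
  })

  len <- vapply(lines, polyline_length, numeric(1))
  keep <- len > 0 | from != to
  if (!any(keep)) stop("empty network", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " zero-length self-loop(s) dropped", call. = FALSE)
    lines <- lines[keep]; from <- from[keep]; to <- to[keep]; len <- len[keep]
  }

  edges <- tibble::tibble(
    edge_id = seq_along(lines),
    from = from,
    to = to,
    length = len,
    geometry = lines
  )
  deg <- tabulate(c(edges$from, edges$to), nbins = nrow(node_xy))
  nodes <- tibble::tibble(
    node_id = seq_len(nrow(node_xy)),
    x = node_xy[, 1],
    y = node_xy[, 2],
    degree = deg
  )
  structure(
    list(nodes = nodes, edges = edges, weld_tolerance = weld_tolerance,
         crs = crs),
    class = "street_network"
  )
}

# Single-linkage weld of a point set within `tol`, via grid hashing +
# connected components. Returns cluster id per point (numbered by first
# appearance) and one representative coordinate per cluster (the mean).
weld_points <- function(pts, tol) {
  n <- nrow(pts)
  if (tol <= 0) {
    key <- paste(pts[, 1], pts[, 2])
    id <- match(key, unique(key))
  } else {
    cx <- floor(pts[, 1] / tol)
    cy <- floor(pts[, 2] / tol)
    idx_by_cell <- split(seq_len(n), paste(cx, cy))
    pairs_i <- integer(0)
    pairs_j <- integer(0)
    for (i in seq_len(n)) {
      cand <- integer(0)
      for (dx in -1:1) {
        for (dy in -1:1) {
          cand <- c(cand, idx_by_cell[[paste(cx[i] + dx, cy[i] + dy)]])
        }
      }
      cand <- cand[cand > i]
      if (length(cand)) {
        d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2
        hit <- cand[d2 <= tol^2]
        pairs_i <- c(pairs_i, rep.int(i, length(hit)))
        pairs_j <- c(pairs_j, hit)
      }
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(pairs_i)) g <- igraph::add_edges(g, rbind(pairs_i, pairs_j))
    comp <- igraph::components(g)$membership
    id <- match(comp, unique(comp))   # renumber by first appearance
  }
  f <- factor(id, levels = seq_len(max(id)))
  xy <- cbind(tapply(pts[, 1], f, mean), tapply(pts[, 2], f, mean))
  list(id = id, xy = unname(xy))
}

#' @export
print.street_network <- function(x, ...) {
  cat("<street_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, total length ", format(round(sum(x$edges$length), 1)),
      " m\n", sep = "")
  invisible(x)
}

#' Snap a point to the nearest location on a street network
#'
#' Finds the nearest point on any edge (ties broken by smallest edge id) and
#' records the edge, the arc-length offset from the edge's first node, and
#' the snap distance. Stands in for address geocoding: home locations are
#' attached to the network before a service area is traced.
#'
#' @param net A `street_network`.
#' @param point Numeric length-2 vector (x, y).
#' @param max_snap Maximum allowed snap distance in metres (default 100).
#' @return A `network_origin` object: list with `point`, `snapped`, `edge_id`,
#'   `offset`, `snap_distance`.
#' @export
snap_to_network <- function(net, point, max_snap = 100) {
  stopifnot(inherits(net, "street_network"))
  point <- as.numeric(point)
  best <- list(dist = Inf)
  for (i in seq_len(nrow(net$edges))) {
    pr <- project_on_polyline(net$edges$geometry[[i]], point)
    if (pr$dist < best$dist - 1e-12) {   # strict improvement: smallest-id tie-break
      best <- list(dist = pr$dist, edge_id = net$edges$edge_id[i],
                   offset = pr$offset, snapped = pr$point)
    }
  }
  if (!is.finite(best$dist) || best$dist > max_snap) {
    stop("no network within snapping distance (nearest ",
         format(round(best$dist, 1)), " m > max_snap ", max_snap, " m)",
         call. = FALSE)
  }
  structure(
    list(point = point, snapped = best$snapped, edge_id = best$edge_id,
         offset = best$offset, snap_distance = best$dist),
    class = "network_origin"
  )
}

# igraph handle with edge weights = lengths (memoised on the object).
network_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$length),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$node_id)
  )
}

# Network distance from an origin to every node: min over leaving the snapped
# edge by either end.
origin_node_distances <- function(net, origin) {
  g <- network_graph(net)
  e <- net$edges[net$edges$edge_id == origin$edge_id, ]
  d2ends <- igraph::distances(g, v = as.character(c(e$from, e$to)))
  pmin(origin$offset + d2ends[1, ], (e$length - origin$offset) + d2ends[2, ])
}

#' Subnetwork reachable within a network distance
#'
#' Computes the part of the network whose every point lies within network
#' distance `distance` of a snapped origin. Edges fully inside the threshold
#' are kept whole; partially reachable edges are truncated by linear
#' referencing along their polylines; an edge reachable from both ends
#' contributes the union of its reachable portions (never double-counted).
#'
#' @param net A `street_network`.
#' @param origin A `network_origin` from [snap_to_network()].
#' @param distance Threshold network distance in metres (default 1000, the
#'   walkable catchment conventionally used for home neighbourhoods).
#' @return A `reachable_subnetwork`: list with `origin`, `distance`, `lines`
#'   (list of coordinate matrices), `edge_portions` (tibble `edge_id`, `s0`,
#'   `s1`), and `total_length` (metres).
#' @export
reachable_subnetwork <- function(net, origin, distance = 1000) {
  stopifnot(inherits(net, "street_network"), inherits(origin, "network_origin"))
  if (!is.numeric(distance) || distance <= 0) stop("distance must be > 0",
                                                   call. = FALSE)
  dn <- origin_node_distances(net, origin)
  dn <- dn[as.character(net$nodes$node_id)]

  portions <- vector("list", nrow(net$edges))
  for (i in seq_len(nrow(net$edges))) {
    len <- net$edges$length[i]
    da <- dn[[as.character(net$edges$from[i])]]
    db <- dn[[as.character(net$edges$to[i])]]
    iv <- list()
    if (is.finite(da) && da < distance) {
      iv[[length(iv) + 1L]] <- c(0, min(len, distance - da))
    }
    if (is.finite(db) && db < distance) {
      iv[[length(iv) + 1L]] <- c(max(0, len - (distance - db)), len)
    }
    if (net$edges$edge_id[i] == origin$edge_id) {
      iv[[length(iv) + 1L]] <- c(max(0, origin$offset - distance),
                                 min(len, origin$offset + distance))
    }
    if (length(iv)) {
      portions[[i]] <- cbind(edge = i, merge_intervals(iv))
    }
  }
  portions <- do.call(rbind, portions)

  lines <- list()
  tab <- NULL
  if (!is.null(portions)) {
    keep <- portions[, 3] - portions[, 2] > 1e-9
    portions <- portions[keep, , drop = FALSE]
    lines <- lapply(seq_len(nrow(portions)), function(k) {
      polyline_substring(net$edges$geometry[[portions[k, 1]]],
                         portions[k, 2], portions[k, 3])
    })
    tab <- tibble::tibble(
      edge_id = net$edges$edge_id[portions[, 1]],
      s0 = portions[, 2], s1 = portions[, 3]
    )
  } else {
    tab <- tibble::tibble(edge_id = integer(), s0 = numeric(), s1 = numeric())
  }
  structure(
    list(origin = origin, distance = distance, lines = lines,
         edge_portions = tab,
         total_length = if (nrow(tab)) sum(tab$s1 - tab$s0) else 0,
         crs = net$crs),
    class = "reachable_subnetwork"
  )
}

# Union of closed intervals given as a list of c(lo, hi).
merge_intervals <- function(iv) {
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (k in seq_len(nrow(m))[-1]) {
    last <- nrow(out)
    if (m[k, 1] <= out[last, 2] + 1e-12) {
      out[last, 2] <- max(out[last, 2], m[k, 2])
    } else {
      out <- rbind(out, m[k, ])
    }
  }
  out
}

#' @export
print.reachable_subnetwork <- function(x, ...) {
  cat("<reachable_subnetwork> D = ", x$distance, " m, ",
      nrow(x$edge_portions), " edge portions, reachable length ",
      format(round(x$total_length, 1)), " m\n", sep = "")
  invisible(x)
}

#' Count street intersections inside a polygon
#'
#' An intersection is a network node with three or more incident edges (the
#' walkability-literature convention for "true" intersections; degree-2
#' vertices are never intersections). Nodes on the polygon boundary count as
#' inside.
#'
#' @param net A `street_network`.
#' @param polygon A `sausage_buffer`, or a region as a polyclip-style ring
#'   list (`list(list(x =, y =))`).
#' @param min_valence Minimum number of incident edges (default 3,
#'   configurable).
#' @return Integer count.
#' @export
count_intersections <- function(net, polygon, min_valence = 3) {
  stopifnot(inherits(net, "street_network"))
  cand <- net$nodes[net$nodes$degree >= min_valence, ]
  if (nrow(cand) == 0L) return(0L)
  if (inherits(polygon, "sausage_buffer")) {
    # exact membership: within offset r of the buffered sub-polylines
    inside <- vapply(seq_len(nrow(cand)), function(i) {
      p <- c(cand$x[i], cand$y[i])
      any(vapply(polygon$subnetwork$lines,
                 function(l) dist_to_polyline(l, p) <= polygon$offset + 1e-9,
                 logical(1)))
    }, logical(1))
  } else {
    inside <- point_in_rings(polygon, cand$x, cand$y)
  }
  sum(inside)
}
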
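# Shared fixtures and independent oracles, all built in code.

# n x n grid of unit-ish blocks: one edge per block side, block length `block`.
grid_lines <- function(n, block = 1) {
  lines <- list()
  for (i in 0:n) {
    for (j in seq_len(n)) {
      lines[[length(lines) + 1L]] <-
        rbind(c((j - 1) * block, i * block), c(j * block, i * block))
    }
  }
  for (j in 0:n) {
    for (i in seq_len(n)) {
      lines[[length(lines) + 1L]] <-
        rbind(c(j * block, (i - 1) * block), c(j * block, i * block))
    }
  }
  lines
}

# Random small connected network: a random spanning tree over random points
# plus a few extra chords, straight-line edges.
random_network <- function(n_nodes = 12, n_extra = 6, span = 2000,
                           seed = 1) {
  withr::local_seed(seed)
  pts <- matrix(runif(2 * n_nodes, 0, span), ncol = 2)
  edges <- list()
  for (k in 2:n_nodes) {           # random tree: attach k to a previous node
    j <- sample(k - 1L, 1)
    edges[[length(edges) + 1L]] <- rbind(pts[j, ], pts[k, ])
  }
  for (k in seq_len(n_extra)) {
    ij <- sample(n_nodes, 2)
    if (sum((pts[ij[1], ] - pts[ij[2], ])^2) > 1e-6) {
      edges[[length(edges) + 1L]] <- pts[ij, ]
    }
  }
  list(lines = edges, points = pts)
}

# Independent reachable-length oracle: subdivide every edge into small pieces,
# take exact shortest-path distances at the subdivision nodes, and accumulate
# each piece's reachable portion from its two ends in closed form.
oracle_reachable_length <- function(lines, origin_xy, D, n_sub = 7) {
  key <- function(p) paste(signif(p[1], 12), signif(p[2], 12))
  nodes <- character(0)
  from <- character(0); to <- character(0); w <- numeric(0)
  pieces <- list()
  for (m in lines) {
    L <- sqrt(sum((m[2, ] - m[1, ])^2))
    for (k in seq_len(n_sub)) {
      a <- m[1, ] + (k - 1) / n_sub * (m[2, ] - m[1, ])
      b <- m[1, ] + k / n_sub * (m[2, ] - m[1, ])
      from <- c(from, key(a)); to <- c(to, key(b)); w <- c(w, L / n_sub)
      pieces[[length(pieces) + 1L]] <- list(a = key(a), b = key(b),
                                            len = L / n_sub)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE
  )
  d <- igraph::distances(g, v = key(origin_xy))[1, ]
  sum(vapply(pieces, function(pc) {
    d1 <- d[[pc$a]]; d2 <- d[[pc$b]]
    min(pc$len,
        max(0, min(pc$len, D - d1)) + max(0, min(pc$len, D - d2)))
  }, numeric(1)))
}

# Random buffer-summary rows (valid by construction) for identity checks.
random_summaries <- function(n, seed = 1) {
  withr::local_seed(seed)
  uses <- dlumr::nonres_land_uses()
  s <- tibble::tibble(
    buffer_area = runif(n, 0.5, 4),
    residential_area = runif(n, 0, 1.5) * rbinom(n, 1, 0.9),
    dwelling_units = rpois(n, 600) * rbinom(n, 1, 0.95),
    intersections = rpois(n, 40)
  )
  for (u in uses) s[[paste0("area_", u)]] <- runif(n, 0, 0.3) * rbinom(n, 1, 0.8)
  for (u in uses) s[[paste0("count_", u)]] <- rpois(n, 15) * rbinom(n, 1, 0.8)
  s
}

# The published 12-site rank matrix used to pin the ranking arithmetic
# (sites as rows, one column per indicator).
published_rank_table <- function() {
  sites <- c("Melbourne", "Ghent", "Curitiba", "Hong Kong", "Hradec Kralove",
             "Olomouc", "Odense", "Auckland", "Wellington", "Valencia",
             "Baltimore", "Seattle")
  m <- rbind(   # one row per indicator, one column per site
    c(6, 9, 4, 1, 7, 11, 2, 5, 3, 8, 10, 12),    # dlum1
    c(3, 6, 1, 11, 7, 4, 2, 5, 8, 12, 9, 10),    # dlum2
    c(4, 5, 1, 8, 7, 6, 2, 9, 10, 3, 11, 12),    # dlum3a
    c(3, 5, 1, 7, 10, 6, 2, 8, 9, 4, 11, 12),    # dlum3b
    c(7, 5, 2, 3, 4, 1, 8, 9, 11, 6, 10, 12),    # dlum4
    c(3, 4, 7, 2, 8, 1, 11, 5, 9, 6, 12, 10),    # dlum5
    c(4, 1, 11, 5, 3, 8, 9, 6, 2, 7, 12, 10),    # dlum6
    c(5, 8, 4, 1, 7, 10, 2, 6, 3, 9, 11, 12),    # dlum7
    c(3, 6, 1, 11, 7, 4, 2, 5, 8, 12, 9, 10),    # dlum8
    c(2, 5, 1, 3, 10, 4, 7, 6, 8, 9, 11, 12),    # dlum9a
    c(2, 6, 1, 3, 10, 7, 5, 4, 8, 9, 11, 12),    # dlum9b
    c(7, 4, 2, 3, 5, 1, 8, 9, 11, 6, 10, 12)     # dlum10
  )
  out <- tibble::tibble(site = sites)
  for (k in seq_along(dlumr::dlum_names())) {
    out[[dlumr::dlum_names()[k]]] <- m[k, ]
  }
  class(out) <- c("rank_table", class(out))
  out
}

published_mean_ranking <- function() {
  c(Melbourne = 4.1, Ghent = 5.3, Curitiba = 3.0, `Hong Kong` = 4.8,
    `Hradec Kralove` = 7.1, Olomouc = 5.3, Odense = 5.0, Auckland = 6.4,
    Wellington = 7.5, Valencia = 7.6, Baltimore = 10.6, Seattle = 11.3)
}

published_sd_ranking <- function() {
  c(Melbourne = 1.8, Ghent = 2.0, Curitiba = 3.1, `Hong Kong` = 3.6,
    `Hradec Kralove` = 2.3, Olomouc = 3.4, Odense = 3.4, Auckland = 1.8,
    Wellington = 3.1, Valencia = 2.8, Baltimore = 1.0, Seattle = 1.0)
}

# A long straight street with parcels laid alongside, sized so the clipped
# areas and counts are known exactly (band of half-width 25 m around y = 0).
strip_city <- function() {
  net <- dlumr::build_network(list(rbind(c(0, 0), c(30000, 0))))
  geoms <- list()
  use <- character(0)
  du <- integer(0)
  add <- function(xmin, ymin, xmax, ymax, u, d = 0L) {
    geoms[[length(geoms) + 1L]] <<-
      rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
    use <<- c(use, u)
    du <<- c(du, d)
  }
  for (k in 0:9) {       # 10 residential parcels, 0.05 km2 and 80 units each
    add(k * 2500, -25, (k + 1) * 2500, -5, "residential", 80L)
  }
  add(26000, 0, 26500, 20, "commercial_retail_office")   # 0.01 km2, inside
  add(27000, 0, 27500, 20, "commercial_retail_office")   # 0.01 km2, inside
  add(1000, 5, 2000, 55, "park")                         # 0.05 km2, 40% in band
  list(net = net, parcels = dlumr::parcels(geoms, use, du))
}

strip_buffer <- function(net, distance = 15000, offset = 25) {
  o <- dlumr::snap_to_network(net, c(15000, 0), max_snap = 10)
  dlumr::sausage_buffer(dlumr::reachable_subnetwork(net, o, distance), offset)
}
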
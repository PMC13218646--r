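#' Configuration of a synthetic city
#'
#' Describes an orthogonal-grid city: a block grid whose streets form the
#' network, each block tiled by rectangular single-use parcels drawn from a
#' land-use mixture, and dwelling-unit counts on residential parcels. The
#' defaults emulate a mid-density mixed-use urban fabric: 150 m blocks, 16
#' parcels per block (about 1400 m^2 each), a little over half the land
#' residential, and negative-binomially dispersed dwelling counts averaging
#' 40 units per residential parcel (roughly 16,000 dwellings/km^2 of
#' residential land, mid-way on the international density spectrum).
#'
#' @param rows,cols Number of block rows/columns (default 6 x 6).
#' @param block Block edge length in metres (default 150).
#' @param parcels_per_side Parcels per block side; each block is tiled by
#'   `parcels_per_side^2` rectangles (default 4).
#' @param mixture Named probability vector over the six land-use classes
#'   (must sum to 1).
#' @param du_mean,du_size Mean and dispersion (size) of the negative-binomial
#'   dwelling-unit draw for residential parcels (a minimum of 1 unit is
#'   enforced).
#' @param seed Integer seed; the whole city is deterministic given the seed.
#' @return A `city_config` list.
#' @export
city_config <- function(rows = 6, cols = 6, block = 150, parcels_per_side = 4,
                        mixture = c(residential = 0.55,
                                    commercial_retail_office = 0.15,
                                    institutional_civic = 0.08,
                                    food_related = 0.10,
                                    entertainment = 0.04,
                                    park = 0.08),
                        du_mean = 40, du_size = 5, seed = 1L) {
  if (rows < 1 || cols < 1 || block <= 0 || parcels_per_side < 1) {
    stop("degenerate city dimensions", call. = FALSE)
  }
  if (!setequal(names(mixture), all_land_uses())) {
    stop("mixture must be named over the six land-use classes", call. = FALSE)
  }
  mixture <- mixture[all_land_uses()]
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture must be a probability vector summing to 1", call. = FALSE)
  }
  structure(
    list(rows = rows, cols = cols, block = block,
         parcels_per_side = parcels_per_side, mixture = mixture,
         du_mean = du_mean, du_size = du_size, seed = as.integer(seed)),
    class = "city_config"
  )
}

#' Generate a synthetic city
#'
#' Builds the grid street network (one edge per block side) and the parcel
#' fabric: every block is subdivided into equal rectangles, each assigned a
#' single land use drawn from the mixture; residential parcels receive
#' dwelling counts from a negative-binomial draw. Fully deterministic given
#' the config seed.
#'
#' @param cfg A [city_config()].
#' @return A `synthetic_city`: list with `network` (a `street_network`),
#'   `parcels` (a `parcels` tibble) and `config`.
#' @export
generate_city <- function(cfg) {
  stopifnot(inherits(cfg, "city_config"))
  withr::local_seed(cfg$seed)
  b <- cfg$block
  # street segments along every grid line, one edge per block side
  lines <- list()
  for (i in 0:cfg$rows) {        # horizontal streets
    for (j in seq_len(cfg$cols)) {
      lines[[length(lines) + 1L]] <-
        rbind(c((j - 1) * b, i * b), c(j * b, i * b))
    }
  }
  for (j in 0:cfg$cols) {        # vertical streets
    for (i in seq_len(cfg$rows)) {
      lines[[length(lines) + 1L]] <-
        rbind(c(j * b, (i - 1) * b), c(j * b, i * b))
    }
  }
  net <- build_network(lines, weld_tolerance = 1e-6, crs = "synthetic-metric")

  s <- cfg$parcels_per_side
  cell <- b / s
  n_parcels <- cfg$rows * cfg$cols * s * s
  geoms <- vector("list", n_parcels)
  k <- 0L
  for (i in seq_len(cfg$rows)) {
    for (j in seq_len(cfg$cols)) {
      x0 <- (j - 1) * b
      y0 <- (i - 1) * b
      for (pi in seq_len(s)) {
        for (pj in seq_len(s)) {
          k <- k + 1L
          geoms[[k]] <- rect_ring(x0 + (pj - 1) * cell, y0 + (pi - 1) * cell,
                                  x0 + pj * cell, y0 + pi * cell)[[1]]
        }
      }
    }
  }
  use <- sample(all_land_uses(), n_parcels, replace = TRUE,
                prob = cfg$mixture)
  du <- integer(n_parcels)
  n_res <- sum(use == "residential")
  du[use == "residential"] <-
    pmax(1L, stats::rnbinom(n_res, mu = cfg$du_mean, size = cfg$du_size))
  p <- parcels(lapply(geoms, list), use, du, crs = "synthetic-metric")
  structure(list(network = net, parcels = p, config = cfg),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("<synthetic_city> ", x$config$rows, "x", x$config$cols, " blocks of ",
      x$config$block, " m, ", nrow(x$parcels), " parcels (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Sample participant home locations
#'
#' Draws `n` home points uniformly within the residential parcels of a city
#' (parcels weighted by area). Deterministic given the seed.
#'
#' @param city A `synthetic_city`.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param site Site label attached to every participant (default the city's
#'   seed as a string); multi-site studies are emulated by generating several
#'   cities with different configs and binding the results.
#' @return Tibble `participant_id`, `site`, `x`, `y`.
#' @export
generate_participants <- function(city, n, seed = 1L,
                                  site = paste0("site", city$config$seed)) {
  stopifnot(inherits(city, "synthetic_city"), n >= 1)
  res <- city$parcels[city$parcels$land_use == "residential", ]
  if (nrow(res) == 0L) stop("city has no residential parcels", call. = FALSE)
  withr::local_seed(seed)
  idx <- sample(nrow(res), n, replace = TRUE, prob = res$area)
  pts <- t(vapply(idx, function(i) {
    bb <- rings_bbox(res$geometry[[i]])
    # rectangular parcels: a single uniform draw lands inside
    repeat {
      q <- c(stats::runif(1, bb[1], bb[3]), stats::runif(1, bb[2], bb[4]))
      if (point_in_rings(res$geometry[[i]], q[1], q[2])) return(q)
    }
  }, numeric(2)))
  tibble::tibble(
    participant_id = seq_len(n),
    site = site,
    x = pts[, 1],
    y = pts[, 2]
  )
}

#' Behavioural simulation parameters
#'
#' Link parameters for the synthetic perception and physical-activity models.
#' Defaults are anchored on typical adolescent travel statistics: a mean
#' weekly non-school active-transport frequency near 5 trips, about 42%
#' prevalence of regular walking to school, and a walking speed of 80 m/min
#' (the common planning convention) for converting network distances into
#' perceived walking-time bands.
#'
#' @param alpha,beta Intercept and slope of the log-linear (Poisson) model of
#'   weekly non-school active-transport frequency on a standardised
#'   indicator.
#' @param alpha_walk,beta_walk Intercept and slope (logit scale) of the
#'   Bernoulli model of regular walking to school.
#' @param misclassification Probability that a perception item score shifts
#'   by one band (clamped to 1..5).
#' @param walking_speed Metres per minute (default 80).
#' @param seed Integer seed.
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(alpha = log(5), beta = 0.3,
                            alpha_walk = stats::qlogis(0.42), beta_walk = 0.4,
                            misclassification = 0.1, walking_speed = 80,
                            seed = 1L) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(alpha_walk),
            is.finite(beta_walk),
            misclassification >= 0, misclassification <= 1,
            walking_speed > 0)
  structure(
    list(alpha = alpha, beta = beta, alpha_walk = alpha_walk,
         beta_walk = beta_walk, misclassification = misclassification,
         walking_speed = walking_speed, seed = as.integer(seed)),
    class = "behavior_config"
  )
}

#' Band walking distances into perceived-proximity scores
#'
#' Converts network distances to the nearest destination of each type into
#' 1-5 perceived proximity scores by walking time: 5 for up to 5 minutes
#' (high accessibility), 4 up to 10, 3 up to 20, 2 up to 30, and 1 beyond 30
#' minutes (low accessibility). With probability `misclassification` a score
#' shifts one band up or down (clamped to 1..5). The composite is the mean of
#' the item scores, mirroring how multi-item perceived-accessibility scales
#' are scored.
#'
#' @param distances Tibble (or data frame) of per-participant network
#'   distances in metres, one column per destination type.
#' @param cfg A [behavior_config()].
#' @return Tibble of per-item scores (`score_<item>`) plus `composite`.
#' @export
simulate_perception <- function(distances, cfg = behavior_config()) {
  stopifnot(inherits(cfg, "behavior_config"))
  d <- as.matrix(distances)
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative",
                                     call. = FALSE)
  withr::local_seed(cfg$seed)
  minutes <- d / cfg$walking_speed
  score <- matrix(1L, nrow(d), ncol(d))
  score[minutes <= 30] <- 2L
  score[minutes <= 20] <- 3L
  score[minutes <= 10] <- 4L
  score[minutes <= 5] <- 5L
  score[is.na(minutes)] <- NA_integer_
  flip <- matrix(stats::runif(length(score)) < cfg$misclassification,
                 nrow(score))
  shift <- matrix(sample(c(-1L, 1L), length(score), replace = TRUE),
                  nrow(score))
  noisy <- pmin(pmax(score + flip * shift, 1L), 5L)
  out <- tibble::as_tibble(as.data.frame(noisy))
  names(out) <- paste0("score_", colnames(d))
  out$composite <- rowMeans(noisy, na.rm = TRUE)
  out
}

#' Simulate physical-activity outcomes from an indicator
#'
#' Generates outcomes with the association structure that construct-validity
#' analyses estimate: weekly non-school active-transport frequency is
#' Poisson with log-mean `alpha + beta * z`, and regular walking to school is
#' Bernoulli with logit `alpha_walk + beta_walk * z`, where `z` is the
#' indicator standardised within site.
#'
#' @param z Standardised indicator values (one per participant).
#' @param cfg A [behavior_config()].
#' @return Tibble `z`, `nonschool_active_transport`, `regular_walking`.
#' @export
simulate_pa <- function(z, cfg = behavior_config()) {
  stopifnot(inherits(cfg, "behavior_config"))
  withr::local_seed(cfg$seed)
  lambda <- exp(cfg$alpha + cfg$beta * z)
  pwalk <- stats::plogis(cfg$alpha_walk + cfg$beta_walk * z)
  tibble::tibble(
    z = z,
    nonschool_active_transport = stats::rpois(length(z), lambda),
    regular_walking = stats::runif(length(z)) < pwalk
  )
}

#' Network distance from each home to the nearest destination of each type
#'
#' Snaps each home and each non-residential parcel centroid to the network
#' and returns, per participant, the shortest network distance to the nearest
#' parcel of each destination group that has a perceived-proximity item
#' (entertainment has none and is skipped by default).
#'
#' @param city A `synthetic_city`.
#' @param homes Tibble with `x`, `y` columns from [generate_participants()].
#' @param types Destination groups to measure (default the four with
#'   perception items).
#' @param max_snap Snapping tolerance in metres passed to
#'   [snap_to_network()].
#' @return Tibble of distances (metres), one column per type.
#' @export
nearest_destination_distances <- function(city, homes,
                                          types = setdiff(nonres_land_uses(),
                                                          "entertainment"),
                                          max_snap = 500) {
  net <- city$network
  g <- network_graph(net)
  edge_ref <- net$edges

  snap_info <- function(px, py) {
    o <- snap_to_network(net, c(px, py), max_snap = max_snap)
    e <- edge_ref[edge_ref$edge_id == o$edge_id, ]
    list(from = e$from, to = e$to, d_from = o$offset,
         d_to = e$length - o$offset, edge_id = o$edge_id, offset = o$offset)
  }

  homes_s <- lapply(seq_len(nrow(homes)),
                    function(i) snap_info(homes$x[i], homes$y[i]))
  node_names <- as.character(net$nodes$node_id)
  dist_nodes <- igraph::distances(g)   # all-pairs once; grid nets are small

  out <- tibble::tibble(.rows = nrow(homes))
  for (ty in types) {
    dest <- city$parcels[city$parcels$land_use == ty, ]
    if (nrow(dest) == 0L) {
      out[[ty]] <- rep(NA_real_, nrow(homes))
      next
    }
    dest_s <- lapply(seq_len(nrow(dest)), function(i) {
      bb <- rings_bbox(dest$geometry[[i]])
      snap_info(mean(bb[c(1, 3)]), mean(bb[c(2, 4)]))
    })
    dvec <- vapply(homes_s, function(h) {
      hi_from <- match(as.character(h$from), node_names)
      hi_to <- match(as.character(h$to), node_names)
      min(vapply(dest_s, function(dd) {
        di_from <- match(as.character(dd$from), node_names)
        di_to <- match(as.character(dd$to), node_names)
        via <- min(
          h$d_from + dist_nodes[hi_from, di_from] + dd$d_from,
          h$d_from + dist_nodes[hi_from, di_to] + dd$d_to,
          h$d_to + dist_nodes[hi_to, di_from] + dd$d_from,
          h$d_to + dist_nodes[hi_to, di_to] + dd$d_to
        )
        if (h$edge_id == dd$edge_id) {
          via <- min(via, abs(h$offset - dd$offset))
        }
        via
      }, numeric(1)))
    }, numeric(1))
    out[[ty]] <- dvec
  }
  out
}
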
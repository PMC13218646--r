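#' Land-use classes
#'
#' The parcel fabric distinguishes residential land from five groups of
#' non-residential land uses: commercial/retail/office, institutional/civic,
#' food-related, entertainment, and parks. Dwelling-unit counts attach only to
#' residential parcels; the five non-residential groups are the numerators of
#' all destination and land-use mix indicators.
#'
#' @format Character vectors.
#' @name land_uses
NULL

#' @rdname land_uses
#' @export
nonres_land_uses <- function() {
  c("commercial_retail_office", "institutional_civic", "food_related",
    "entertainment", "park")
}

#' @rdname land_uses
#' @export
all_land_uses <- function() c("residential", nonres_land_uses())

#' Construct a parcel table
#'
#' @param geometry List of parcel polygons, each a polyclip-style ring list or
#'   a single coordinate matrix (treated as one outer ring).
#' @param land_use Character vector of classes, one of [all_land_uses()].
#' @param dwelling_units Non-negative integer counts; must be 0 for
#'   non-residential parcels.
#' @param parcel_id Optional ids (default sequential).
#' @param crs Optional projected-CRS label carried with the geometries.
#' @return A `parcels` tibble with columns `parcel_id`, `land_use`,
#'   `dwelling_units`, `area` (m^2) and a `geometry` list-column of ring
#'   lists.
#' @export
parcels <- function(geometry, land_use, dwelling_units = 0L,
                    parcel_id = seq_along(geometry), crs = NULL) {
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(list(x = g[, 1], y = g[, 2]))
    g
  })
  land_use <- as.character(land_use)
  bad <- setdiff(unique(land_use), all_land_uses())
  if (length(bad)) stop("unknown land use class(es): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  dwelling_units <- as.integer(rep_len(dwelling_units, length(geometry)))
  if (any(dwelling_units < 0)) stop("dwelling_units must be non-negative",
                                    call. = FALSE)
  if (any(dwelling_units > 0 & land_use != "residential")) {
    stop("dwelling_units > 0 on a non-residential parcel", call. = FALSE)
  }
  area <- vapply(geometry, function(g) abs(rings_area(g)), numeric(1))
  if (any(area <= 0)) stop("parcel polygons must have positive area",
                           call. = FALSE)
  out <- tibble::tibble(
    parcel_id = parcel_id,
    land_use = land_use,
    dwelling_units = dwelling_units,
    area = area,
    geometry = geometry
  )
  attr(out, "crs") <- crs
  class(out) <- c("parcels", class(out))
  out
}

#' Select parcels intersecting a sausage buffer
#'
#' A parcel is included when it overlaps the buffer with positive area; each
#' included parcel carries its clipped area (area of the intersection with
#' the buffer) and a count contribution of exactly 1 regardless of overlap
#' fraction, so area ratios stay geometrically consistent while counts treat
#' a parcel touched by the walkable street fabric as one destination.
#'
#' @param p A `parcels` tibble.
#' @param buffer A `sausage_buffer`.
#' @param count_mode How a boundary-straddling parcel contributes its count:
#'   `"intersects"` (any positive-area overlap counts 1, default),
#'   `"centroid"` (counts only if its centroid falls in the buffer), or
#'   `"majority"` (counts only if at least half its area is inside).
#' @return The included rows of `p` with extra columns `clipped_area` (m^2)
#'   and `count` (0/1 under the chosen mode).
#' @export
select_parcels <- function(p, buffer, count_mode = c("intersects", "centroid",
                                                     "majority")) {
  stopifnot(inherits(buffer, "sausage_buffer"))
  count_mode <- match.arg(count_mode)
  crs_p <- attr(p, "crs")
  if (!is.null(crs_p) && !is.null(buffer$crs) &&
      !identical(crs_p, buffer$crs)) {
    stop("CRS mismatch: parcels in '", crs_p, "', buffer in '",
         buffer$crs, "'", call. = FALSE)
  }
  bb <- rings_bbox(buffer$rings)
  res <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    g <- p$geometry[[i]]
    pb <- rings_bbox(g)
    if (pb[1] > bb[3] || pb[3] < bb[1] || pb[2] > bb[4] || pb[4] < bb[2]) {
      return(NULL)
    }
    clip <- rings_intersection(g, buffer$rings)
    a <- rings_area(clip)
    if (a <= 1e-6) return(NULL)          # zero-area (boundary) contact excluded
    row <- p[i, ]
    row$clipped_area <- a
    row$count <- switch(
      count_mode,
      intersects = 1L,
      centroid = {
        cx <- mean(vapply(g, function(r) mean(r$x), numeric(1)))
        cy <- mean(vapply(g, function(r) mean(r$y), numeric(1)))
        as.integer(point_in_rings(buffer$rings, cx, cy))
      },
      majority = as.integer(a >= 0.5 * p$area[i])
    )
    row
  })
  if (nrow(res) == 0L) {
    res <- p[0, ]
    res$clipped_area <- numeric(0)
    res$count <- integer(0)
  }
  attr(res, "buffer_area") <- buffer$area
  res
}

#' Aggregate a parcel selection into a per-buffer summary
#'
#' Produces the one-row table of areas, counts, dwelling units and
#' intersections that feeds every indicator: clipped areas per land use
#' (km^2), whole-parcel counts per non-residential use, the dwelling-unit
#' total of included residential parcels, the intersection count, and the
#' total buffer area (km^2).
#'
#' @param selection Output of [select_parcels()] on the same buffer.
#' @param buffer The `sausage_buffer` used for the selection.
#' @param net The `street_network` (for intersection counting).
#' @param min_valence Intersection valence passed to [count_intersections()].
#' @return A one-row `buffer_summary` tibble with columns `buffer_area`,
#'   `residential_area`, `area_<use>` and `count_<use>` for the five
#'   non-residential uses, `dwelling_units`, `intersections`. Areas in km^2.
#' @export
summarize_buffer <- function(selection, buffer, net, min_valence = 3) {
  stopifnot(inherits(buffer, "sausage_buffer"),
            inherits(net, "street_network"))
  uses <- nonres_land_uses()
  m2_to_km2 <- 1e-6
  area_by <- vapply(uses, function(u) {
    sum(selection$clipped_area[selection$land_use == u]) * m2_to_km2
  }, numeric(1))
  count_by <- vapply(uses, function(u) {
    sum(selection$count[selection$land_use == u])
  }, numeric(1))
  res_rows <- selection$land_use == "residential"
  out <- tibble::tibble(
    buffer_area = buffer$area * m2_to_km2,
    residential_area = sum(selection$clipped_area[res_rows]) * m2_to_km2,
    dwelling_units = sum(selection$dwelling_units[res_rows] *
                           selection$count[res_rows]),
    intersections = count_intersections(net, buffer, min_valence)
  )
  for (u in uses) out[[paste0("area_", u)]] <- area_by[[u]]
  for (u in uses) out[[paste0("count_", u)]] <- count_by[[u]]
  class(out) <- c("buffer_summary", class(out))
  out
}

# Column helpers shared by the indicator layer.
area_cols <- function() paste0("area_", nonres_land_uses())
count_cols <- function() paste0("count_", nonres_land_uses())

#' Density metrics of a buffer summary
#'
#' Net residential density (dwellings per km^2 of residential land), street
#' intersection density (intersections per km^2 of total buffer area), and
#' gross parcel density of each of the five non-residential land uses
#' (parcels per km^2 of total buffer area).
#'
#' A buffer with no residential land has an undefined net residential density:
#' the value is `NA` with a reason code, never 0 or infinity.
#'
#' @param s A `buffer_summary` tibble (one or more rows).
#' @return A tibble with `net_residential_density`, `intersection_density`,
#'   `gross_density_<use>` columns and an `undefined_reason` character column
#'   (`NA` when everything is defined).
#' @export
density_metrics <- function(s) {
  if (any(s$buffer_area <= 0)) stop("buffer_area must be > 0", call. = FALSE)
  nrd <- ifelse(s$residential_area > 0,
                s$dwelling_units / s$residential_area, NA_real_)
  out <- tibble::tibble(
    net_residential_density = nrd,
    intersection_density = s$intersections / s$buffer_area
  )
  for (u in nonres_land_uses()) {
    out[[paste0("gross_density_", u)]] <- s[[paste0("count_", u)]] / s$buffer_area
  }
  out$undefined_reason <- ifelse(
    s$residential_area > 0, NA_character_,
    "net_residential_density:no_residential_land"
  )
  out
}
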
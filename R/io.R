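# GeoJSON reading/writing on top of jsonlite, plus the tabular writers.
# Only planar (projected metric) coordinates are accepted: a file whose
# coordinates all fit inside lon/lat bounds, or that declares a geographic
# CRS, is rejected rather than silently reprojected.

geojson_parse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  crs_name <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) &&
      grepl("CRS84|4326|WGS ?84", crs_name, ignore.case = TRUE)) {
    stop("projected metric CRS required: ", path, " declares geographic CRS '",
         crs_name, "'", call. = FALSE)
  }
  gj
}

coords_mat <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read a street network from GeoJSON
#'
#' Reads a LineString/MultiLineString FeatureCollection (projected metric
#' CRS) and welds it into a [build_network()] street network. Node and edge
#' counts are reported via message.
#'
#' @param path Path to a GeoJSON file.
#' @param weld_tolerance Endpoint welding tolerance in metres.
#' @param quiet Suppress the node/edge count message.
#' @return A `street_network`.
#' @export
read_network <- function(path, weld_tolerance = 0.01, quiet = FALSE) {
  gj <- geojson_parse(path)
  if (length(gj$features) == 0L) stop("empty network", call. = FALSE)
  lines <- list()
  bad <- character(0)
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    ty <- f$geometry$type
    id <- if (!is.null(f$id)) f$id else i
    if (identical(ty, "LineString")) {
      lines[[length(lines) + 1L]] <- coords_mat(f$geometry$coordinates)
    } else if (identical(ty, "MultiLineString")) {
      for (part in f$geometry$coordinates) {
        lines[[length(lines) + 1L]] <- coords_mat(part)
      }
    } else {
      bad <- c(bad, paste0(id, " (", ty, ")"))
    }
  }
  if (length(bad)) {
    stop("mixed geometry types: non-line feature(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  all_xy <- do.call(rbind, lines)
  assert_projected(all_xy[, 1], all_xy[, 2], what = path)
  net <- build_network(lines, weld_tolerance = weld_tolerance,
                       crs = "projected-metric")
  if (!quiet) {
    message("read_network: ", nrow(net$nodes), " nodes, ",
            nrow(net$edges), " edges from ", path)
  }
  net
}

#' Read parcels from GeoJSON
#'
#' Reads a Polygon/MultiPolygon FeatureCollection and maps the source
#' land-use codes onto the six classes via a mapping configuration. Every
#' code present in the file must be mapped or the run aborts listing the
#' unmapped codes.
#'
#' @param path Path to a GeoJSON file.
#' @param mapping Either `NULL` (codes already use the six class names), a
#'   named list/vector `source code -> class` plus
#'   attribute names, or a path to a YAML file with fields `codes` (mapping),
#'   `land_use_field` (property holding the source code, default
#'   `"land_use"`) and `dwelling_field` (property holding dwelling units,
#'   default `"dwelling_units"`).
#' @param repair How to treat invalid (self-intersecting / zero-area ring)
#'   geometries: `"drop"` (default, with a message) or `"error"`.
#' @return A `parcels` tibble.
#' @export
read_parcels <- function(path, mapping = NULL, repair = c("drop", "error")) {
  repair <- match.arg(repair)
  if (is.null(mapping)) {       # identity mapping over the six classes
    mapping <- list(codes = as.list(stats::setNames(all_land_uses(),
                                                    all_land_uses())))
  }
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  if (is.null(mapping$codes)) mapping <- list(codes = mapping)
  lu_field <- mapping$land_use_field %||% "land_use"
  du_field <- mapping$dwelling_field %||% "dwelling_units"
  codes <- unlist(mapping$codes)

  gj <- geojson_parse(path)
  feats <- gj$features
  if (length(feats) == 0L) stop("no parcel features in ", path, call. = FALSE)

  seen <- unique(vapply(feats, function(f) {
    as.character(f$properties[[lu_field]] %||% NA_character_)
  }, character(1)))
  unmapped <- setdiff(seen, names(codes))
  if (length(unmapped)) {
    stop("unmapped land-use code(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }

  geoms <- list(); use <- character(0); du <- integer(0); ids <- character(0)
  dropped <- 0L
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ty <- f$geometry$type
    rings_raw <- if (identical(ty, "Polygon")) {
      list(f$geometry$coordinates)
    } else if (identical(ty, "MultiPolygon")) {
      f$geometry$coordinates
    } else {
      stop("feature ", i, " is not a Polygon/MultiPolygon (", ty, ")",
           call. = FALSE)
    }
    rings <- list()
    for (poly in rings_raw) {
      for (k in seq_along(poly)) {
        m <- coords_mat(poly[[k]])
        # drop the closing vertex GeoJSON repeats
        if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
        r <- list(x = m[, 1], y = m[, 2])
        # outer rings first and positive, holes negative
        sa <- ring_signed_area(r)
        if (k == 1L && sa < 0) r <- list(x = rev(r$x), y = rev(r$y))
        if (k > 1L && sa > 0) r <- list(x = rev(r$x), y = rev(r$y))
        rings[[length(rings) + 1L]] <- r
      }
    }
    ok <- length(rings) > 0 && rings_area(rings) > 0
    if (!ok) {
      if (repair == "error") stop("invalid geometry in feature ", i,
                                  call. = FALSE)
      dropped <- dropped + 1L
      next
    }
    geoms[[length(geoms) + 1L]] <- rings
    use <- c(use, codes[[as.character(f$properties[[lu_field]])]])
    duv <- f$properties[[du_field]] %||% 0L
    du <- c(du, as.integer(duv))
    ids <- c(ids, as.character(f$id %||% i))
  }
  if (dropped > 0L) message("read_parcels: dropped ", dropped,
                            " invalid geometr", if (dropped == 1) "y" else "ies")
  all_xy <- do.call(rbind, lapply(geoms, function(g) {
    cbind(unlist(lapply(g, `[[`, "x")), unlist(lapply(g, `[[`, "y")))
  }))
  assert_projected(all_xy[, 1], all_xy[, 2], what = path)
  parcels(geoms, use, du, parcel_id = ids, crs = "projected-metric")
}

#' Read participant home points
#'
#' Accepts a CSV with `x`, `y` (and optional `participant_id`, `site`)
#' columns, or a GeoJSON Point FeatureCollection with those properties.
#'
#' @param path Path to a CSV or GeoJSON file.
#' @return Tibble `participant_id`, `site`, `x`, `y`.
#' @export
read_homes <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- geojson_parse(path)
    out <- purrr::map_dfr(seq_along(gj$features), function(i) {
      f <- gj$features[[i]]
      if (!identical(f$geometry$type, "Point")) {
        stop("feature ", i, " is not a Point", call. = FALSE)
      }
      tibble::tibble(
        participant_id = f$properties$participant_id %||% i,
        site = as.character(f$properties$site %||% "site1"),
        x = f$geometry$coordinates[[1]],
        y = f$geometry$coordinates[[2]]
      )
    })
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("x", "y") %in% names(out))) {
      stop("homes CSV needs x and y columns", call. = FALSE)
    }
    if (!"participant_id" %in% names(out)) {
      out$participant_id <- seq_len(nrow(out))
    }
    if (!"site" %in% names(out)) out$site <- "site1"
    out <- out[, c("participant_id", "site", "x", "y")]
  }
  assert_projected(out$x, out$y, what = path)
  out
}

# ---- writers -------------------------------------------------------------

geojson_feature <- function(geometry, properties = NULL) {
  list(type = "Feature",
       properties = if (is.null(properties)) structure(list(), names = character(0)) else properties,
       geometry = geometry)
}

geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

ring_to_coords <- function(r) {
  n <- length(r$x)
  c(lapply(seq_len(n), function(i) c(r$x[i], r$y[i])), list(c(r$x[1], r$y[1])))
}

#' Write spatial objects to GeoJSON
#'
#' `write_network_geojson()` writes one LineString feature per edge;
#' `write_parcels_geojson()` one Polygon feature per parcel (holes as inner
#' rings); `write_buffer_geojson()` the dissolved sausage polygon, for visual
#' inspection in any GIS.
#'
#' @param net,p,buffer The object to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @name geojson_writers
NULL

#' @rdname geojson_writers
#' @export
write_network_geojson <- function(net, path) {
  feats <- lapply(seq_len(nrow(net$edges)), function(i) {
    m <- net$edges$geometry[[i]]
    geojson_feature(
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(k) m[k, ])),
      properties = list(edge_id = net$edges$edge_id[i],
                        length = net$edges$length[i])
    )
  })
  geojson_write(feats, path)
}

#' @rdname geojson_writers
#' @export
write_parcels_geojson <- function(p, path) {
  feats <- lapply(seq_len(nrow(p)), function(i) {
    geojson_feature(
      list(type = "Polygon",
           coordinates = lapply(p$geometry[[i]], ring_to_coords)),
      properties = list(parcel_id = p$parcel_id[i],
                        land_use = p$land_use[i],
                        dwelling_units = p$dwelling_units[i])
    )
  })
  geojson_write(feats, path)
}

#' @rdname geojson_writers
#' @export
write_buffer_geojson <- function(buffer, path) {
  # group holes with the outer ring they fall in
  sa <- vapply(buffer$rings, ring_signed_area, numeric(1))
  outers <- which(sa > 0)
  holes <- which(sa < 0)
  polys <- lapply(outers, function(o) {
    ring <- buffer$rings[[o]]
    inner <- holes[vapply(holes, function(h) {
      all(point_in_rings(list(ring), buffer$rings[[h]]$x[1],
                         buffer$rings[[h]]$y[1]))
    }, logical(1))]
    c(list(ring), buffer$rings[inner])
  })
  feats <- list(geojson_feature(
    list(type = "MultiPolygon",
         coordinates = lapply(polys, function(poly) {
           lapply(poly, ring_to_coords)
         })),
    properties = list(offset = buffer$offset,
                      distance = buffer$subnetwork$distance,
                      area_m2 = buffer$area)
  ))
  geojson_write(feats, path)
}
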
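#' Land-use mix entropy index
#'
#' Normalised Shannon entropy of the distribution of land (or parcel counts)
#' across the non-residential land-use categories:
#' \deqn{-\sum_k p_k \ln p_k / \ln N}
#' where \eqn{p_k} is the proportion held by category \eqn{k} and \eqn{N} is
#' the number of categories in the classification scheme (5 by default) --
#' not the number of categories present, so the index stays comparable across
#' buffers. The index ranges from 0 (a single land use) to 1 (an even
#' distribution, e.g. 20% of each of five land uses). Zero proportions
#' contribute nothing (the \eqn{0 \ln 0 := 0} limit convention).
#'
#' @param values Non-negative amounts per category (areas or parcel counts);
#'   a vector, or a matrix/data frame with one row per composition.
#' @param n_categories The fixed category number \eqn{N} of the scheme
#'   (default 5).
#' @return Entropy value(s) in `[0, 1]`; `NA` for an all-zero composition
#'   (the mix of nothing is undefined, not 0).
#' @examples
#' entropy_lum(c(0.2, 0.2, 0.2, 0.2, 0.2))  # 1
#' entropy_lum(c(1, 0, 0, 0, 0))            # 0
#' entropy_lum(c(0.5, 0.5, 0, 0, 0))        # log(2)/log(5)
#' @export
entropy_lum <- function(values, n_categories = 5) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (any(values < 0, na.rm = TRUE)) {
    stop("composition values must be non-negative", call. = FALSE)
  }
  total <- rowSums(values)
  p <- values / total
  terms <- ifelse(p > 0, p * log(p), 0)
  h <- -rowSums(terms) / log(n_categories)
  # the index is bounded in [0, 1] by construction; clamp the residual
  # floating-point error so the even composition is exactly 1
  h <- pmin(pmax(h, 0), 1) + 0   # `+ 0` normalises IEEE negative zero
  h[total <= 0] <- NA_real_
  unname(h)
}

#' Destination intensity indicators (DLUM 1-4)
#'
#' The five intensity indicators derived from a buffer summary:
#' * `dlum1` -- ratio of the summed land areas of the 5 non-residential uses
#'   to the residential land area of the buffer;
#' * `dlum2` -- ratio of the summed parcel counts of the 5 uses to the
#'   dwelling-unit count, scaled by `du_scale` (per 100 dwellings by
#'   default, the reporting convention);
#' * `dlum3a` -- summed parcel count of the 5 uses;
#' * `dlum3b` -- gross density: `dlum3a` divided by the buffer area
#'   (parcels/km^2);
#' * `dlum4` -- net density: `dlum3a` divided by the summed areas of the 5
#'   uses (parcels/km^2 of non-residential land).
#'
#' Zero denominators yield `NA` with a reason code (no residential land, no
#' dwellings, or no non-residential land), never 0 or infinity, so downstream
#' ranking can distinguish "no residential land" from "no destinations".
#'
#' @param s A `buffer_summary` tibble (any number of rows).
#' @param du_scale Dwelling-unit scaling of `dlum2` (default 100).
#' @return Tibble with `dlum1`, `dlum2`, `dlum3a`, `dlum3b`, `dlum4` and an
#'   `undefined_reason` column.
#' @export
intensity_indicators <- function(s, du_scale = 100) {
  nonres_area <- rowSums(as.matrix(s[, area_cols()]))
  nonres_count <- rowSums(as.matrix(s[, count_cols()]))
  out <- tibble::tibble(
    dlum1 = ifelse(s$residential_area > 0, nonres_area / s$residential_area,
                   NA_real_),
    dlum2 = ifelse(s$dwelling_units > 0,
                   nonres_count / s$dwelling_units * du_scale, NA_real_),
    dlum3a = nonres_count,
    dlum3b = nonres_count / s$buffer_area,
    dlum4 = ifelse(nonres_area > 0, nonres_count / nonres_area, NA_real_)
  )
  reasons <- cbind(
    ifelse(s$residential_area > 0, NA, "dlum1:no_residential_land"),
    ifelse(s$dwelling_units > 0, NA, "dlum2:no_dwelling_units"),
    ifelse(nonres_area > 0, NA, "dlum4:no_nonresidential_area")
  )
  out$undefined_reason <- apply(reasons, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else NA_character_
  })
  out
}

#' Hybrid intensity-by-heterogeneity indicators (DLUM 7-10)
#'
#' Each hybrid indicator weights an intensity indicator by one plus a
#' land-use-mix entropy index: `dlum7 = dlum1 * (1 + dlum5)` (area-based
#' mix), and `dlum8/9a/9b/10 = dlum2/3a/3b/4 * (1 + dlum6)` (parcel-count
#' based mix). An undefined operand propagates `NA`.
#'
#' @param intensity Tibble with `dlum1`, `dlum2`, `dlum3a`, `dlum3b`,
#'   `dlum4` (as from [intensity_indicators()]).
#' @param dlum5 Area-based LUM entropy values.
#' @param dlum6 Parcel-count-based LUM entropy values.
#' @return Tibble with `dlum7`, `dlum8`, `dlum9a`, `dlum9b`, `dlum10`.
#' @export
hybrid_indicators <- function(intensity, dlum5, dlum6) {
  tibble::tibble(
    dlum7 = intensity$dlum1 * (1 + dlum5),
    dlum8 = intensity$dlum2 * (1 + dlum6),
    dlum9a = intensity$dlum3a * (1 + dlum6),
    dlum9b = intensity$dlum3b * (1 + dlum6),
    dlum10 = intensity$dlum4 * (1 + dlum6)
  )
}

#' Compute the full vector of 12 DLUM indicators
#'
#' Assembles, for each buffer summary row, the twelve destination and
#' land-use mix indicators -- five intensity measures (`dlum1`, `dlum2`,
#' `dlum3a`, `dlum3b`, `dlum4`), two land-use-mix entropy indices (`dlum5`
#' from the area composition, `dlum6` from the parcel-count composition) and
#' five hybrid measures (`dlum7`-`dlum10`) -- together with the auxiliary
#' density metrics.
#'
#' @inheritParams intensity_indicators
#' @param n_categories Category number of the land-use classification for the
#'   entropy denominators (default 5).
#' @return A tibble with one row per summary row and the 12 `dlum*` columns,
#'   `net_residential_density`, `intersection_density`,
#'   `gross_density_<use>` columns and `undefined_reason`.
#' @export
compute_indicator_vector <- function(s, du_scale = 100, n_categories = 5) {
  intens <- intensity_indicators(s, du_scale = du_scale)
  dlum5 <- entropy_lum(s[, area_cols()], n_categories = n_categories)
  dlum6 <- entropy_lum(s[, count_cols()], n_categories = n_categories)
  hyb <- hybrid_indicators(intens, dlum5, dlum6)
  dens <- density_metrics(s)
  reasons <- cbind(
    intens$undefined_reason,
    ifelse(is.na(dlum5), "dlum5:no_nonresidential_area", NA),
    ifelse(is.na(dlum6), "dlum6:no_nonresidential_parcels", NA),
    dens$undefined_reason
  )
  reason <- apply(reasons, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else NA_character_
  })
  dplyr::bind_cols(
    intens[c("dlum1", "dlum2", "dlum3a", "dlum3b", "dlum4")],
    tibble::tibble(dlum5 = dlum5, dlum6 = dlum6),
    hyb,
    dens[setdiff(names(dens), "undefined_reason")],
    tibble::tibble(undefined_reason = reason)
  )
}

#' Names of the 12 DLUM indicator columns
#' @return Character vector `dlum1` ... `dlum10`.
#' @export
dlum_names <- function() {
  c("dlum1", "dlum2", "dlum3a", "dlum3b", "dlum4", "dlum5", "dlum6",
    "dlum7", "dlum8", "dlum9a", "dlum9b", "dlum10")
}
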
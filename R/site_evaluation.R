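#' Per-site means of indicator values
#'
#' Collapses participant-level indicator rows to one row per site by the
#' arithmetic mean, ignoring undefined (`NA`) values. A cell where every
#' participant value is undefined stays missing.
#'
#' @param data Tibble of participant rows with a site column and indicator
#'   columns.
#' @param indicators Character vector of indicator column names (default the
#'   12 DLUM columns present in `data`).
#' @param site Name of the site-label column (default `"site"`).
#' @param sites Optional vector of allowed site labels; labels in `data`
#'   outside this set raise an error.
#' @return Tibble with one row per site and one column per indicator.
#' @export
site_means <- function(data, indicators = intersect(dlum_names(), names(data)),
                       site = "site", sites = NULL) {
  if (!site %in% names(data)) stop("no '", site, "' column", call. = FALSE)
  if (!is.null(sites)) {
    bad <- setdiff(unique(data[[site]]), sites)
    if (length(bad)) stop("unknown site label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::group_by(.data[[site]]) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(indicators),
      ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)
    ), .groups = "drop") |>
    dplyr::rename(site = dplyr::all_of(site))
}

#' Rank sites on each indicator
#'
#' Within each indicator column, the site with the largest mean receives rank
#' 1 (the convention under which the best-supplied site "outperforms" the
#' others); ties receive average ranks, so every column's ranks sum to
#' n(n+1)/2.
#'
#' @param site_table Output of [site_means()]: one row per site, indicator
#'   columns.
#' @param indicators Indicator columns to rank (default all DLUM columns
#'   present).
#' @param na_skip If `FALSE` (default) a missing cell is an error; if `TRUE`
#'   missing cells are left `NA` and that column's remaining sites are ranked.
#' @return A `rank_table` tibble: `site` plus one rank column per indicator.
#' @seealso [ranking_summary()] for the per-site mean and SD of ranks.
#' @export
rank_sites <- function(site_table,
                       indicators = intersect(dlum_names(), names(site_table)),
                       na_skip = FALSE) {
  if (nrow(site_table) < 2L) stop("need at least 2 sites to rank",
                                  call. = FALSE)
  out <- tibble::tibble(site = site_table$site)
  for (ind in indicators) {
    v <- site_table[[ind]]
    if (anyNA(v) && !na_skip) {
      stop("missing site mean for indicator '", ind,
           "' (set na_skip = TRUE to rank the remaining sites)",
           call. = FALSE)
    }
    out[[ind]] <- rank(-v, ties.method = "average", na.last = "keep")
  }
  class(out) <- c("rank_table", class(out))
  out
}

#' Summarise a rank table per site
#'
#' For each site, the mean ranking across indicators and the sample standard
#' deviation (n - 1 denominator) of its ranks. The mean of the mean rankings
#' over all sites is always (n_sites + 1) / 2.
#'
#' @param rank_table A `rank_table` from [rank_sites()], or any tibble with a
#'   `site` column and rank columns.
#' @return Tibble with `site`, `mean_ranking`, `sd_ranking`.
#' @export
ranking_summary <- function(rank_table) {
  ranks <- as.matrix(rank_table[, setdiff(names(rank_table), "site")])
  tibble::tibble(
    site = rank_table$site,
    mean_ranking = rowMeans(ranks, na.rm = TRUE),
    sd_ranking = apply(ranks, 1, stats::sd, na.rm = TRUE)
  )
}

#' Rank table in report layout
#'
#' Transposes a rank table to the conventional report shape: one row per
#' indicator, one column per site, plus "Mean ranking" and "Standard
#' deviation of ranking" rows.
#'
#' @param rank_table A `rank_table` from [rank_sites()].
#' @param digits Decimals for the summary rows (default 1).
#' @return Tibble with an `indicator` column and one column per site.
#' @export
rank_report <- function(rank_table, digits = 1) {
  summ <- ranking_summary(rank_table)
  inds <- setdiff(names(rank_table), "site")
  body <- purrr::map_dfr(inds, function(ind) {
    row <- tibble::tibble(indicator = ind)
    for (i in seq_len(nrow(rank_table))) {
      row[[as.character(rank_table$site[i])]] <- rank_table[[ind]][i]
    }
    row
  })
  mean_row <- tibble::tibble(indicator = "Mean ranking")
  sd_row <- tibble::tibble(indicator = "Standard deviation of ranking")
  for (i in seq_len(nrow(summ))) {
    s <- as.character(summ$site[i])
    mean_row[[s]] <- round(summ$mean_ranking[i], digits)
    sd_row[[s]] <- round(summ$sd_ranking[i], digits)
  }
  dplyr::bind_rows(body, mean_row, sd_row)
}

#' Pairwise correlations between indicators
#'
#' Spearman rank correlations (robust to the indicators' typically skewed
#' distributions) over pairwise-complete observations; configurable to
#' Pearson. A constant column has no defined correlation and yields `NA`.
#'
#' @param data Participant-level tibble with indicator columns.
#' @param indicators Columns to correlate (default the DLUM columns present).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
indicator_correlations <- function(data,
                                   indicators = intersect(dlum_names(),
                                                          names(data)),
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- as.matrix(data[, indicators])
  if (sum(stats::complete.cases(m)) < 3L) {
    stop("need at least 3 complete rows", call. = FALSE)
  }
  suppressWarnings(
    stats::cor(m, use = "pairwise.complete.obs", method = method)
  )
}

#' Derive physical-activity outcome flags from raw trip records
#'
#' Applies the classification rules used for adolescent travel behaviour:
#' regular walking to/from school and regular active transport to/from school
#' are defined as 5+ weekly trips (walking, and walking plus cycling,
#' respectively); days per week with at least 60 minutes of physical activity
#' must lie in 0..7.
#'
#' @param data Tibble with non-negative integer columns `walk_school` and
#'   `cycle_school` (weekly trips), and optionally `nonschool_active_transport`
#'   (weekly trip frequency) and `pa_days` (days/week meeting the 60-min
#'   guideline).
#' @param threshold Weekly-trip threshold for "regular" (default 5).
#' @return `data` with logical columns `regular_walking` and
#'   `regular_active_transport` appended.
#' @export
derive_pa_outcomes <- function(data, threshold = 5) {
  need <- c("walk_school", "cycle_school")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  num <- intersect(c(need, "nonschool_active_transport", "pa_days"),
                   names(data))
  for (cl in num) {
    if (any(data[[cl]] < 0, na.rm = TRUE)) {
      stop("negative values in '", cl, "'", call. = FALSE)
    }
  }
  if ("pa_days" %in% names(data) && any(data$pa_days > 7, na.rm = TRUE)) {
    stop("pa_days must be in 0..7", call. = FALSE)
  }
  data |>
    dplyr::mutate(
      regular_walking = .data$walk_school >= threshold,
      regular_active_transport =
        (.data$walk_school + .data$cycle_school) >= threshold
    )
}

# Spearman rho of x against y (complete pairs assumed).
spearman_rho <- function(x, y) {
  suppressWarnings(stats::cor(rank(x), rank(y), method = "pearson"))
}

#' Construct-validity association of an indicator with a criterion
#'
#' Formalises the qualitative evaluation criterion "a consistent correlate in
#' the expected direction and across sites": per site, the Spearman rank
#' correlation between an indicator and a criterion measure (a perception
#' composite or a physical-activity outcome) with permutation p-values; the
#' overall verdict is `"consistent-positive"` when every site's correlation
#' is positive and no site's permutation test finds evidence of a negative
#' association at `alpha`, `"mixed"` otherwise.
#'
#' @param data Tibble with indicator, criterion and site columns.
#' @param indicator,outcome Column names (strings).
#' @param site Site column name (default `"site"`).
#' @param n_perm Number of permutations (default 999).
#' @param alpha Significance level of the one-sided negative-association test
#'   (default 0.05).
#' @param min_pairs Minimum complete pairs per site; smaller sites are
#'   skipped with a warning (default 10).
#' @param seed Seed for the permutation draws.
#' @return A `dlum_validity` object; see [tidy.dlum_validity()] and
#'   [glance.dlum_validity()].
#' @export
validity_association <- function(data, indicator, outcome, site = "site",
                                 n_perm = 999, alpha = 0.05, min_pairs = 10,
                                 seed = 1L) {
  stopifnot(indicator %in% names(data), outcome %in% names(data),
            site %in% names(data))
  withr::local_seed(seed)
  per_site <- purrr::map_dfr(
    split(data, data[[site]]),
    function(d) {
      ok <- stats::complete.cases(d[[indicator]], d[[outcome]])
      x <- d[[indicator]][ok]
      y <- d[[outcome]][ok]
      if (length(x) < min_pairs) {
        warning("site '", d[[site]][1], "' skipped: only ", length(x),
                " complete pairs", call. = FALSE)
        return(NULL)
      }
      pt <- permutation_rho_test(x, y, n_perm)
      tibble::tibble(
        site = d[[site]][1], n = length(x), rho = pt$rho,
        p_positive = pt$p_positive, p_negative = pt$p_negative
      )
    }
  )
  if (nrow(per_site) == 0L) stop("no site had enough complete pairs",
                                 call. = FALSE)
  verdict <- if (all(per_site$rho > 0) && all(per_site$p_negative > alpha)) {
    "consistent-positive"
  } else {
    "mixed"
  }
  structure(
    list(per_site = per_site, verdict = verdict, indicator = indicator,
         outcome = outcome, n_perm = n_perm, alpha = alpha, seed = seed),
    class = "dlum_validity"
  )
}

# One-sided permutation p-values for a Spearman correlation; the criterion
# values are permuted, the indicator ranks held fixed.
permutation_rho_test <- function(x, y, n_perm) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- suppressWarnings(stats::cor(rx, ry))
  perm <- replicate(n_perm, sample(ry))
  rho_b <- suppressWarnings(as.vector(stats::cor(rx, perm)))
  list(
    rho = obs,
    p_positive = (1 + sum(rho_b >= obs, na.rm = TRUE)) / (n_perm + 1),
    p_negative = (1 + sum(rho_b <= obs, na.rm = TRUE)) / (n_perm + 1)
  )
}

#' @export
print.dlum_validity <- function(x, ...) {
  cat("<dlum_validity> ", x$indicator, " ~ ", x$outcome, " by site\n",
      sep = "")
  print(x$per_site)
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Tidy a construct-validity fit
#'
#' @param x A `dlum_validity` object.
#' @param ... Unused.
#' @return Per-site tibble: `site`, `n`, `rho`, `p_positive`, `p_negative`.
#' @export
tidy.dlum_validity <- function(x, ...) x$per_site

#' One-line summary of a construct-validity fit
#'
#' @param x A `dlum_validity` object.
#' @param ... Unused.
#' @return One-row tibble: `indicator`, `outcome`, `n_sites`, `min_rho`,
#'   `max_rho`, `verdict`.
#' @export
glance.dlum_validity <- function(x, ...) {
  tibble::tibble(
    indicator = x$indicator, outcome = x$outcome,
    n_sites = nrow(x$per_site),
    min_rho = min(x$per_site$rho), max_rho = max(x$per_site$rho),
    verdict = x$verdict
  )
}

#' Heatmap of a rank table
#'
#' @param object A `rank_table`.
#' @param ... Unused.
#' @return A ggplot tile map, sites ordered by mean ranking.
#' @export
autoplot.rank_table <- function(object, ...) {
  summ <- ranking_summary(object)
  long <- tidyr::pivot_longer(object, -"site", names_to = "indicator",
                              values_to = "rank")
  long$site <- factor(long$site,
                      levels = summ$site[order(summ$mean_ranking)])
  long$indicator <- factor(long$indicator,
                           levels = setdiff(names(object), "site"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$indicator, y = .data$site,
                                     fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
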